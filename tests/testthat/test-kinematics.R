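test_that("torso frame follows the stated axis conventions", {
  fr <- torso_frame(neck = c(0, 0, 1), shoulder_L = c(0.2, 0, 0.9),
                    shoulder_R = c(-0.2, 0, 0.9), hip = c(0, 0, 0))
  expect_equal(fr$Z, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$X, c(0, -1, 0), tolerance = 1e-12)
  expect_equal(fr$Y, c(1, 0, 0), tolerance = 1e-12)
})

test_that("torso frame is orthonormal, right-handed and rotation-equivariant", {
  set.seed(21)
  for (i in 1:20) {
    pts <- list(neck = c(0, 0, 1) + rnorm(3, 0, 0.05),
                sL = c(0.2, 0.03, 0.9) + rnorm(3, 0, 0.05),
                sR = c(-0.2, -0.02, 0.88) + rnorm(3, 0, 0.05),
                hip = rnorm(3, 0, 0.05))
    fr <- torso_frame(pts$neck, pts$sL, pts$sR, pts$hip)
    M <- rbind(fr$X, fr$Y, fr$Z)
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-9)
    expect_equal(sum(cross3(fr$X, fr$Y) * fr$Z), 1, tolerance = 1e-9)

    Q <- random_rotation()
    fr2 <- torso_frame(Q %*% pts$neck, Q %*% pts$sL, Q %*% pts$sR,
                       Q %*% pts$hip)
    expect_equal(fr2$Z, as.numeric(Q %*% fr$Z), tolerance = 1e-9)
    expect_equal(fr2$X, as.numeric(Q %*% fr$X), tolerance = 1e-9)
  }
})

test_that("degenerate torso configurations are rejected", {
  expect_error(torso_frame(c(0, 0, 0), c(0.2, 0, 0.9), c(-0.2, 0, 0.9),
                           c(0, 0, 0)), "neck coincides|degenerate")
  expect_error(torso_frame(c(0, 0, 1), c(0, 0, 0.4), c(0, 0, 0.8),
                           c(0, 0, 0)), "collinear")
})

test_that("hip flexion spans 0 (neutral) to 180 (fully raised)", {
  fr <- torso_frame(c(0, 0, 0.5), c(0.2, 0, 0.45), c(-0.2, 0, 0.45),
                    c(0, 0, 0))
  expect_equal(hip_flexion_angle(fr, c(0, 0, 0), c(0, 0, -0.45)), 0,
               tolerance = 1e-12)
  expect_equal(hip_flexion_angle(fr, c(0, 0, 0), c(0, 0, 0.45)), 180,
               tolerance = 1e-12)
  expect_equal(hip_flexion_angle(fr, c(0, 0, 0), c(0.45, 0, 0)), 90,
               tolerance = 1e-12)
  expect_error(hip_flexion_angle(fr, c(0, 0, 0), c(0, 0, 0)), "femur")
})

test_that("knee flexion is the angle between femur and tibia axes", {
  expect_equal(knee_flexion_angle(c(0, 0, 1), c(0, 0, 0.5), c(0, 0, 0)), 0,
               tolerance = 1e-12)
  expect_equal(knee_flexion_angle(c(0, 0, 1), c(0, 0, 0.5), c(0, 0, 1)),
               180, tolerance = 1e-12)
  expect_equal(knee_flexion_angle(c(0, 0, 1), c(0, 0, 0.5),
                                  c(0.5, 0, 0.5)), 90, tolerance = 1e-12)
  expect_error(knee_flexion_angle(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0)),
               "femur")
})

test_that("trunk side bend is signed left-positive against the floor", {
  expect_equal(trunk_side_bend_angle(c(0, 0.2, 1), c(0, -0.2, 1)), 0)
  # left shoulder 0.1 m lower over 0.1732 m horizontal separation -> +30
  expect_equal(trunk_side_bend_angle(c(0, 0.1732, 0.9),
                                     c(0, 0, 1)),
               atan2(0.1, 0.1732) * 180 / pi, tolerance = 1e-9)
  expect_equal(trunk_side_bend_angle(c(0, 0.1732, 1.0),
                                     c(0, 0, 0.9)),
               -atan2(0.1, 0.1732) * 180 / pi, tolerance = 1e-9)
  expect_error(trunk_side_bend_angle(c(0, 0, 1), c(0, 0, 0.5)),
               "horizontal")
})

test_that("all angles are rigid-motion, mirror and scale invariant", {
  set.seed(9)
  params <- skeleton_params()
  tr <- generate_angle_profile(motion_profile("side_dip_left", 30))
  skel <- forward_kinematics(params, tr)
  ybt <- forward_kinematics(params, generate_angle_profile(
    motion_profile("ybt_hip_extension", 35)))

  frame_angles <- function(P) {
    fr <- torso_frame(P["neck", ], P["shoulder_L", ], P["shoulder_R", ],
                      P["hip_R", ])
    c(hip = hip_flexion_angle(fr, P["hip_R", ], P["knee_R", ]),
      knee = knee_flexion_angle(P["hip_R", ], P["knee_R", ], P["ankle_R", ]),
      bend = trunk_side_bend_angle(P["shoulder_L", ], P["shoulder_R", ]))
  }

  for (i in c(1, 15, 31)) {
    P <- skel$xyz[i, , ]
    base <- frame_angles(P)

    # rotation about the vertical axis + translation preserves all angles
    # (the side-bend reference plane is the horizontal floor)
    th <- runif(1, 0, 2 * pi)
    Qz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    d <- rnorm(3)
    Pz <- t(apply(P, 1, function(x) Qz %*% x + d))
    dimnames(Pz) <- dimnames(P)
    expect_equal(frame_angles(Pz), base, tolerance = 1e-9)

    # hip and knee angles are invariant under arbitrary rigid motions
    Q <- random_rotation()
    Pq <- t(apply(P, 1, function(x) Q %*% x + d))
    dimnames(Pq) <- dimnames(P)
    Pybt <- ybt$xyz[i, , ]
    Pybt_q <- t(apply(Pybt, 1, function(x) Q %*% x + d))
    dimnames(Pybt_q) <- dimnames(Pybt)
    expect_equal(frame_angles(Pq)[c("hip", "knee")],
                 base[c("hip", "knee")], tolerance = 1e-9)
    expect_equal(frame_angles(Pybt_q)[c("hip", "knee")],
                 frame_angles(Pybt)[c("hip", "knee")], tolerance = 1e-9)

    # sagittal-plane mirror (y -> -y): a reflection is an isometry, so with
    # the shoulder labels swapped it negates the side bend and preserves
    # the hip and knee angles of the same physical points
    Pm <- P
    Pm[, 2] <- -Pm[, 2]
    Pm[c("shoulder_L", "shoulder_R"), ] <-
      Pm[c("shoulder_R", "shoulder_L"), ]
    ang_m <- frame_angles(Pm)
    expect_equal(ang_m[["bend"]], -base[["bend"]], tolerance = 1e-9)
    expect_equal(ang_m[c("hip", "knee")], base[c("hip", "knee")],
                 tolerance = 1e-9)

    # uniform scaling changes no angle
    Ps <- P * 2.73
    expect_equal(frame_angles(Ps), base, tolerance = 1e-9)
  }
})

test_that("trace extraction handles missing keypoints per contract", {
  params <- skeleton_params()
  tr <- generate_angle_profile(motion_profile("ybt_hip_extension", 35))
  skel <- forward_kinematics(params, tr)
  skel$xyz[7, "knee_R", ] <- NA # missing knee at one frame
  out <- angle_trace_from_skeleton(skel, "ybt_hip_extension")
  expect_true(is.na(out$angle_deg[7]))
  expect_false(any(is.na(out$angle_deg[-7])))

  no_ankle <- skel
  no_ankle$xyz <- no_ankle$xyz[, setdiff(dimnames(skel$xyz)[[2]], "knee_R"), ]
  expect_error(angle_trace_from_skeleton(no_ankle, "ybt_hip_extension"),
               "knee_R")
})
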