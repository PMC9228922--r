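test_that("canonicalisation centres the neck and normalises by body height", {
  f <- hand_frame(0)
  sk <- canonicalise(f, NULL, 704)
  expect_equal(nrow(sk$joints), 14)
  expect_equal(sk$joints[2, ], c(0, 0))
  expect_equal(sk$body_height, 50 / 704, tolerance = 1e-12)
  # independent arithmetic: (p - neck) / |neck - hip_mid| in pixels
  kp <- hand_keypoints()[1:14, 1:2]
  expected <- sweep(kp, 2, kp[2, ]) / 50
  expect_equal(unname(sk$joints), unname(expected), tolerance = 1e-12)
  expect_equal(static_features(sk), as.vector(t(expected)),
               tolerance = 1e-12)
})

test_that("canonical joints are invariant to pixel translation and uniform
           scaling about the neck", {
  f <- hand_frame(0)
  base <- canonicalise(f, NULL, 704)

  kp_t <- hand_keypoints()
  kp_t[, 1] <- kp_t[, 1] + 50
  kp_t[, 2] <- kp_t[, 2] + 30
  shifted <- canonicalise(hand_frame(0, kp_t), NULL, 704)
  expect_equal(shifted$joints, base$joints, tolerance = 1e-9)

  kp_s <- hand_keypoints()
  neck <- kp_s[2, 1:2]
  kp_s[, 1:2] <- sweep(2 * sweep(kp_s[, 1:2], 2, neck), 2, -neck)
  scaled <- canonicalise(hand_frame(0, kp_s), NULL, 704)
  expect_equal(scaled$joints, base$joints, tolerance = 1e-9)
})

test_that("missing joints are carried over from the previous skeleton", {
  f0 <- hand_frame(0)
  sk0 <- canonicalise(f0, NULL, 704)
  kp <- hand_keypoints()
  kp[5, 3] <- 0   # right wrist lost
  sk1 <- canonicalise(hand_frame(1, kp), sk0, 704)
  expect_true(sk1$missing_mask[5])
  expect_equal(sk1$joints[5, ], sk0$joints[5, ])
  # on a first frame with no predecessor the joint sits at the origin
  sk_first <- canonicalise(hand_frame(0, kp), NULL, 704)
  expect_equal(sk_first$joints[5, ], c(0, 0))

  # degenerate pose: hips coincide with the neck
  kp_d <- hand_keypoints()
  kp_d[c(9, 12), 1:2] <- rep(kp_d[2, 1:2], each = 2)
  expect_error(canonicalise(hand_frame(0, kp_d), NULL, 704), "degenerate")
  # unusable first frame: no neck, no shoulders to synthesise one
  kp_n <- hand_keypoints()
  kp_n[2, 3] <- 0
  expect_error(canonicalise(hand_frame(0, kp_n), NULL, 704), "unusable")
})

test_that("feature vectors have the published dimensions", {
  f <- hand_frame(0)
  sk <- canonicalise(f, NULL, 704)
  expect_length(static_features(sk), 28)
  expect_length(motion_features(sk, sk, c(1, 1), 704), 68)
  expect_length(geometric_features(sk), 62)
  blocks <- geometric_feature_blocks(sk)
  expect_equal(lengths(blocks),
               c(limb_orientation = 13L, limb_length = 13L,
                 inner_angle = 13L, long_length = 13L, end_length = 10L))
  # 10 end lengths = all pairs among the 5 end joints
  expect_equal(length(blocks$end_length), choose(5, 2))
})

test_that("motion features carry body, joint and box velocity as specified", {
  f0 <- hand_frame(0)
  sk0 <- canonicalise(f0, NULL, 704)
  # identical skeletons, zero box velocity -> all zeros
  expect_equal(motion_features(sk0, sk0, c(0, 0), 704), rep(0, 68))

  # whole body moves +3 px in x: joint velocities vanish in body
  # coordinates, body velocity = 3/704 in each of the 10 x-slots
  kp1 <- hand_keypoints()
  kp1[, 1] <- kp1[, 1] + 3
  sk1 <- canonicalise(hand_frame(1, kp1), sk0, 704)
  mf <- motion_features(sk1, sk0, NULL, 704)
  expect_equal(mf[1:28], rep(0, 28), tolerance = 1e-12)
  expect_equal(mf[29:48], rep(c(3 / 704, 0), 10), tolerance = 1e-12)
  expect_equal(mf[49:68], rep(0, 20))

  # box velocity (2, 1) px/frame: divided by width then body height (50 px
  # wide-normalised = 50/704), so x-slots = (2/704)/(50/704) = 2/50
  mf2 <- motion_features(sk0, sk0, c(2, 1), 704)
  expect_equal(mf2[49:68], rep(c(2 / 50, 1 / 50), 10), tolerance = 1e-12)
})

test_that("inner angles and long lengths match trigonometric oracles", {
  # straight right arm: shoulder, elbow, wrist collinear -> angle pi
  kp <- hand_keypoints()
  kp["r_shoulder", 1:2] <- c(112, 80)
  kp["r_elbow", 1:2] <- c(112, 100)
  kp["r_wrist", 1:2] <- c(112, 120)
  g <- geometric_feature_blocks(canonicalise(hand_frame(0, kp), NULL, 704))
  expect_equal(g$inner_angle[3], pi, tolerance = 1e-9)

  # right-angle elbow: limbs perpendicular
  kp["r_wrist", 1:2] <- c(132, 100)
  g <- geometric_feature_blocks(canonicalise(hand_frame(0, kp), NULL, 704))
  expect_equal(g$inner_angle[3], pi / 2, tolerance = 1e-9)
  l1 <- g$limb_length[4]   # shoulder-elbow
  l2 <- g$limb_length[5]   # elbow-wrist
  expect_equal(g$long_length[3], sqrt(l1^2 + l2^2), tolerance = 1e-9)
})

test_that("static and geometric features obey the invariance properties", {
  set.seed(7)
  for (rep in 1:10) {
    f <- random_frame()
    base <- canonicalise(f, NULL, 704)
    sf <- static_features(base)
    gb <- geometric_feature_blocks(base)

    # translation
    kp <- f$keypoints
    kp[, 1:2] <- sweep(kp[, 1:2], 2, stats::runif(2, -40, 40), `-`)
    tr <- canonicalise(hand_frame(0, kp), NULL, 704)
    expect_equal(static_features(tr), sf, tolerance = 1e-9)
    expect_equal(geometric_features(tr), geometric_features(base),
                 tolerance = 1e-9)

    # uniform scaling about the neck
    kp <- f$keypoints
    s <- stats::runif(1, 0.5, 2.5)
    neck <- kp[2, 1:2]
    kp[, 1:2] <- sweep(s * sweep(kp[, 1:2], 2, neck), 2, -neck)
    sc <- canonicalise(hand_frame(0, kp), NULL, 704)
    gs <- geometric_feature_blocks(sc)
    expect_equal(static_features(sc), sf, tolerance = 1e-6)
    for (blk in c("limb_length", "inner_angle", "long_length", "end_length",
                  "limb_orientation"))
      expect_equal(gs[[blk]], gb[[blk]], tolerance = 1e-6)

    # global rotation: orientations shift by theta (mod 2 pi), the other
    # blocks are unchanged
    theta <- stats::runif(1, -pi, pi)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    kp <- f$keypoints
    kp[, 1:2] <- t(R %*% t(sweep(kp[, 1:2], 2, neck))) + rep(neck, each = 18)
    ro <- canonicalise(hand_frame(0, kp), NULL, 704)
    gr <- geometric_feature_blocks(ro)
    dphi <- (gr$limb_orientation - gb$limb_orientation - theta) %% (2 * pi)
    dphi <- pmin(dphi, 2 * pi - dphi)
    expect_equal(dphi, rep(0, 13), tolerance = 1e-6)
    for (blk in c("limb_length", "inner_angle", "long_length", "end_length"))
      expect_equal(gr[[blk]], gb[[blk]], tolerance = 1e-6)
  }
})

test_that("feature windows span 30 steps with edge-repeat padding", {
  s <- generate_action("Stand", 2, motion_params(seed = 2))
  expect_length(s$frames, 60)
  w <- window_features(s, 30, 704)
  expect_equal(dim(w$branch_a), c(30, 96))
  expect_equal(dim(w$branch_b), c(30, 62))

  # centred at the first frame: steps 1..15 are copies of frame 1
  w1 <- window_features(s, 1, 704)
  for (k in 2:15) expect_equal(w1$branch_a[k, ], w1$branch_a[1, ])
  expect_false(isTRUE(all.equal(w1$branch_a[16, ], w1$branch_a[1, ])))

  # interior window: no padding, steps differ under noise
  expect_false(isTRUE(all.equal(w$branch_a[1, ], w$branch_a[2, ])))

  short <- s
  short$frames <- short$frames[1]
  expect_error(window_features(short, 1, 704), "at least 2")
})

test_that("a zero-motion sequence yields zero motion features", {
  p <- motion_params(noise_sigma = 0, joint_dropout_rate = 0, seed = 3)
  s <- generate_action("Stand", 1, p)
  sk <- canonicalise_sequence(s, 704)
  for (i in 2:length(sk)) {
    mf <- motion_features(sk[[i]], sk[[i - 1]],
                          s$frames[[i]]$box_velocity, 704)
    expect_equal(mf, rep(0, 68), tolerance = 1e-9)
  }
})
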