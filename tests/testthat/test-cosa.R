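test_that("orientation normalization is the identity when the PC is right", {
  pop <- make_population(synth_params(n_specimens = 2, seed = 3),
                         clouds = FALSE)
  sp <- normalize_orientation(pop[1, ])
  expect_false(sp$flip_applied)
  expect_identical(sp$centerline[[1]], pop$centerline[[1]])
})

test_that("normalization is an involution and recovers mirrored specimens", {
  pop <- make_population(synth_params(n_specimens = 1, seed = 8),
                         clouds = FALSE)
  flipped <- mirror_specimen(pop[1, ])
  fixed <- normalize_orientation(flipped)
  expect_true(fixed$flip_applied)
  expect_equal(fixed$centerline[[1]]$y_nm, pop$centerline[[1]]$y_nm)
  # applying normalization again changes nothing
  again <- normalize_orientation(fixed)
  expect_false(again$flip_applied)
  expect_equal(again$centerline[[1]], fixed$centerline[[1]])
})

test_that("rod asymmetry serves as the chirality proxy without a PC marker", {
  pop <- make_population(synth_params(n_specimens = 1, seed = 12),
                         clouds = FALSE)
  flipped <- mirror_specimen(pop[1, ])
  flipped$landmarks[[1]]$pc_axis <- NULL
  fixed <- normalize_orientation(flipped)
  expect_true(fixed$flip_applied)
  expect_equal(fixed$centerline[[1]]$y_nm, pop$centerline[[1]]$y_nm)

  # no PC and symmetric rods: no usable marker
  bare <- pop[1, ]
  bare$landmarks[[1]]$pc_axis <- NULL
  bare$landmarks[[1]]$rod_right <- bare$landmarks[[1]]$rod_left
  expect_error(normalize_orientation(bare), "chirality marker")
})

test_that("deflection thresholds map to the four categories", {
  mk <- function(D) {
    s <- seq(0, 50000, by = 100)
    # linear-in-s deflection whose arclength mean is D * L
    tibble::tibble(s_nm = s, x_nm = s, y_nm = 2 * D * s)
  }
  expect_equal(as.character(classify_bend(mk(0))$category), "straight")
  expect_equal(as.character(classify_bend(mk(0.05))$category), "slight_right")
  expect_equal(as.character(classify_bend(mk(-0.05),
                                          head_neck_angle_deg = 10)$category),
               "mild_left")
  expect_equal(as.character(classify_bend(mk(-0.15),
                                          head_neck_angle_deg = 40)$category),
               "sharp_left")
  # a sharp rightward deflection stays slight_right but raises the flag
  res <- classify_bend(mk(0.15))
  expect_equal(as.character(res$category), "slight_right")
  expect_true(res$sharp_right_flag)
  # subtype requires the kink angle
  expect_error(classify_bend(mk(-0.15)), "head_neck_angle_deg")
})

test_that("subtypes split left bends by kink dominance", {
  mk <- function(D) {
    s <- seq(0, 50000, by = 100)
    tibble::tibble(s_nm = s, x_nm = s, y_nm = 2 * D * s)
  }
  expect_equal(as.character(classify_bend(mk(-0.15),
                                          head_neck_angle_deg = 35)$subtype),
               "type1")
  expect_equal(as.character(classify_bend(mk(-0.15),
                                          head_neck_angle_deg = 20)$subtype),
               "type2")
  expect_equal(as.character(classify_bend(mk(0.05))$subtype), "none")
})

test_that("mirror flip swaps left and right categories", {
  p <- synth_params()
  wf <- make_waveform("mild_left", p, psi = -0.5)
  a <- classify_bend(wf, head_neck_angle_deg = 10)
  b <- classify_bend(mirror_specimen(wf), head_neck_angle_deg = -10)
  expect_equal(as.character(a$category), "mild_left")
  expect_equal(as.character(b$category), "slight_right")
})

test_that("noise-free specimens classify back to their true class exactly", {
  p <- noiseless_params(n_specimens = 60, seed = 21)
  pop <- make_population(p, clouds = FALSE)
  cls <- classify_population(pop)
  expect_identical(as.character(cls$category),
                   as.character(pop$beat_class_true))
  # with noise-free landmarks the subtype also matches the imposed kink
  left <- pop$beat_class_true %in% c("sharp_left", "mild_left")
  expected_subtype <- ifelse(abs(pop$head_neck_angle_true[left]) >= 30,
                             "type1", "type2")
  expect_identical(as.character(cls$subtype[left]), expected_subtype)
})

test_that("classification agrees with ground truth at default noise", {
  pop <- make_population(synth_params(n_specimens = 150, seed = 6),
                         clouds = FALSE)
  cls <- classify_population(pop)
  agree <- mean(as.character(cls$category) ==
                  as.character(pop$beat_class_true))
  expect_gte(agree, 0.95)
  expect_equal(sum(cls$sharp_right_flag), 0)
})

test_that("population distribution counts exactly and validates input", {
  expect_error(population_distribution(character(0)), "empty")
  d <- population_distribution(rep("straight", 10))
  expect_equal(d$fraction, c(0, 0, 1, 0))
  mixed <- c(rep("sharp_left", 2), rep("mild_left", 3), rep("straight", 4),
             rep("slight_right", 1))
  d2 <- population_distribution(mixed)
  expect_equal(d2$n, c(2L, 3L, 4L, 1L))
  expect_equal(sum(d2$fraction), 1)

  cls <- draw_beat_classes(10000, synth_params()$class_weights, seed = 31)
  d3 <- population_distribution(cls)
  w <- synth_params()$class_weights
  expect_true(all(abs(d3$fraction - w) <= 3 * sqrt(w * (1 - w) / 10000)))
})
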