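test_that("profiles of constant images are constant", {
  m <- matrix(4.2, 300, 300)
  w <- well_geometry(97.5, 97.5, 60)
  p <- radial_profile(m, w, 0.65)
  expect_true(all(abs(p$intensity - 4.2) < 1e-12))
  expect_true(all(diff(p$positions) > 0))
  expect_gte(length(p$positions), 16)
})

test_that("a centred radial Gaussian folds to its analytic section", {
  px <- 0.65
  n <- 301
  c_um <- ((n - 1) / 2) * px
  g <- pixel_grids(n, n, px)
  sig <- 20
  m <- 10 + 90 * exp(-((g$x - c_um)^2 + (g$y - c_um)^2) / (2 * sig^2))
  w <- well_geometry(c_um, c_um, 80)
  p <- radial_profile(m, w, px, fold = TRUE)
  expected <- 10 + 90 * exp(-p$positions^2 / (2 * sig^2))
  expect_lt(max(abs(p$intensity - expected)), 0.05)
})

test_that("the 8-line average is invariant under rotation by pi/8", {
  px <- 1
  n <- 241
  c_um <- (n - 1) / 2
  g <- pixel_grids(n, n, px)
  # asymmetric smooth field and its pi/8-rotated copy, evaluated analytically
  f <- function(x, y) 20 + 10 * sin(x / 17) + 6 * cos(y / 23) + x * y / 4000
  th <- pi / 8
  xr <- c_um + cos(th) * (g$x - c_um) - sin(th) * (g$y - c_um)
  yr <- c_um + sin(th) * (g$x - c_um) + cos(th) * (g$y - c_um)
  w <- well_geometry(c_um, c_um, 90)
  p1 <- radial_profile(f(g$x, g$y), w, px)
  p2 <- radial_profile(f(xr, yr), w, px)
  expect_lt(max(abs(p1$intensity - p2$intensity)), 0.15)
})

test_that("folding an unfolded profile reproduces the folded one exactly", {
  sp <- quick_well_spec(seed = 21, actin_class = "peripheral")
  r <- render_microwell_image(sp, channels = "actin")
  w <- well_geometry(r$truth$well$cx, r$truth$well$cy, r$truth$well$R)
  a <- r$image$channels$actin
  folded <- radial_profile(a, w, sp$pixel_size, fold = TRUE)
  unfolded <- radial_profile(a, w, sp$pixel_size, fold = FALSE)
  refolded <- fold_profile(unfolded)
  expect_identical(refolded$intensity, folded$intensity)
  expect_identical(refolded$positions, folded$positions)
})

test_that("small wells are refused as under-sampled", {
  w <- well_geometry(50, 50, 4)
  expect_error(radial_profile(matrix(1, 200, 200), w, 0.65),
               "under-sampled")
})

test_that("archetypal profiles are classified by their defining shapes", {
  r <- seq(0, 75, by = 0.65)
  mk <- function(v) structure(list(positions = r, intensity = v, n_lines = 8,
                                   folded = TRUE, R = 75),
                              class = "actin_profile")
  edge <- 40 + 60 * exp(-(r - 0.95 * 75)^2 / (2 * 6^2))
  ctr <- 40 + 60 * exp(-r^2 / (2 * 22.5^2))
  expect_identical(classify_architecture(mk(edge))$class, "peripheral")
  expect_identical(classify_architecture(mk(ctr))$class, "central")
  expect_identical(classify_architecture(mk(rep(40, length(r))))$class,
                   "uniform")
  # weak fallback: mild, sub-threshold contrast with a non-flat profile
  mild <- 40 + 14 * exp(-r^2 / (2 * 30^2)) + 8 * sin(r / 3)
  cls <- classify_architecture(mk(mild))
  if (cls$weak) expect_true(cls$class %in% c("central", "peripheral"))
  short <- structure(list(positions = r[1:10], intensity = rep(1, 10),
                          n_lines = 8, folded = TRUE, R = 75),
                     class = "actin_profile")
  expect_error(classify_architecture(short), "16 samples")
})

test_that("classification is invariant under gain and tolerable offsets", {
  for (cl in c("uniform", "peripheral", "central")) {
    sp <- quick_well_spec(seed = 31, actin_class = cl, noise_sd = 2)
    r <- render_microwell_image(sp, channels = "actin")
    w <- well_geometry(r$truth$well$cx, r$truth$well$cy, r$truth$well$R)
    base <- subtract_background(r$image$channels$actin, "flat_percentile", 25)
    lab0 <- classify_architecture(radial_profile(base, w, sp$pixel_size))$class
    expect_identical(lab0, cl)
    # gain applied to the raw image; the flat background estimate scales too
    gained <- subtract_background(3 * r$image$channels$actin,
                                  "flat_percentile", 25)
    lab1 <- classify_architecture(radial_profile(gained, w, sp$pixel_size))$class
    expect_identical(lab1, lab0)
  }
})

test_that("architecture proportions tabulate and recover cohort frequencies", {
  d <- architecture_distribution(c(rep("central", 20), rep("uniform", 7),
                                   rep("peripheral", 5)))
  expect_equal(d$proportion[d$class == "central"], 0.625)
  expect_equal(sum(d$proportion), 1)
  one <- architecture_distribution(rep("uniform", 5))
  expect_equal(one$proportion[one$class == "uniform"], 1)
  expect_error(architecture_distribution(character(0)), "label")

  # noise-free generator cohort drawn 50/30/20: classification is exact, so
  # recovered proportions match the draw; the draw matches the probabilities
  # within binomial error
  set.seed(99)
  n <- 200
  classes <- sample(c("uniform", "peripheral", "central"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  est <- character(n)
  for (i in seq_len(n)) {
    sp <- quick_well_spec(seed = 7000 + i, actin_class = classes[i])
    r <- render_microwell_image(sp, channels = "actin")
    w <- well_geometry(r$truth$well$cx, r$truth$well$cy, r$truth$well$R)
    a <- subtract_background(r$image$channels$actin, "flat_percentile", 25)
    est[i] <- classify_architecture(radial_profile(a, w, sp$pixel_size))$class
  }
  expect_identical(est, classes)
  props <- architecture_distribution(est)
  for (cl in c("uniform", "peripheral", "central")) {
    p0 <- c(uniform = 0.5, peripheral = 0.3, central = 0.2)[[cl]]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(props$proportion[props$class == cl] - p0), 3 * se)
  }
})
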