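# LGE thresholding, chordwise transmurality, and segment-model construction.

test_that("FWHM threshold matches the closed form on a two-level phantom", {
  g <- build_lv_geometry(n_slices = 5, endo_radius = 16, epi_radius = 24,
                         matrix_size = 64)
  rm_ <- region_map(g)
  lge <- synthesize_lge(g, rm_, seed = 1, remote_sd = 0, remote_mean = 100,
                        infarct_mean = 300)
  m <- fwhm_infarct_mask(lge)
  expect_equal(m$threshold, 200)
  expect_identical(m$mask, lge$infarct_truth)

  # uniform myocardium: no enhancement, empty mask with a notice
  flat <- lge
  flat$data <- array(100 + rnorm(length(flat$data), sd = 1e-3),
                     dim(flat$data))
  expect_message(m0 <- fwhm_infarct_mask(flat), "no myocardial enhancement")
  expect_equal(sum(m0$mask), 0)
})

test_that("FWHM recovers the scar on the noisy phantom (Dice >= 0.9)", {
  fx <- phantom_fixture()
  m <- fx$infarct
  truth <- fx$lge$infarct_truth
  dice <- 2 * sum(m$mask & truth) / (sum(m$mask) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("n-SD mask applies the remote statistics", {
  set.seed(10)
  data <- array(rnorm(1000, 100, 10), c(10, 10, 10))
  myo <- array(TRUE, c(10, 10, 10))
  data[1:2, 1:2, 1] <- 300
  remote <- myo; remote[1:2, 1:2, 1] <- FALSE
  m <- nsd_infarct_mask(data, 3, remote_region = remote, myo_mask = myo)
  mu <- mean(data[remote]); sdv <- sd(data[remote])
  expect_equal(m$threshold, mu + 3 * sdv)
  expect_true(all(m$mask[1:2, 1:2, 1]))
  expect_lt(mean(m$mask[remote]), 0.01)
})

test_that("chord transmurality honours the strict 50% rule at the boundary", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  endo <- cbind(10 * cos(th), 10 * sin(th))
  epi <- cbind(20 * cos(th), 20 * sin(th))
  ax <- (seq_len(128) - 64.5) * 0.5
  # mask occupying exactly the outer half of the wall everywhere
  dist <- sqrt(outer(ax^2, ax^2, "+"))
  half <- dist > 15 & dist <= 20
  ch <- chord_transmurality(half, endo, epi, ax, n_chords = 72, step = 0.05)
  expect_true(all(abs(ch$fraction - 0.5) < 0.02))
  # clamp to exactly 0.5: strictly greater than 0.5 is required
  ch$fraction <- 0.5
  ch$transmural <- ch$valid & ch$fraction > 0.5
  expect_false(any(ch$transmural))
  # empty mask: all fractions zero
  ch0 <- chord_transmurality(array(FALSE, dim(half)), endo, epi, ax)
  expect_true(all(ch0$fraction == 0))
  expect_false(any(ch0$transmural))
})

test_that("a 90%-transmural wedge is recovered within one chord spacing", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  endo <- cbind(10 * cos(th), 10 * sin(th))
  epi <- cbind(20 * cos(th), 20 * sin(th))
  ax <- (seq_len(192) - 96.5) * 0.25
  dist <- sqrt(outer(ax^2, ax^2, "+"))
  ang <- atan2(outer(rep(1, 192), ax), outer(ax, rep(1, 192)))
  wedge <- dist > 10 & dist < 19 & ang > 40 * pi / 180 & ang < 100 * pi / 180
  ch <- chord_transmurality(wedge, endo, epi, ax, n_chords = 120, step = 0.05)
  b <- find_transmural_borders(ch)
  spacing <- 2 * pi / 120
  expect_lt(abs(wrap_pi(b["theta1"] - 40 * pi / 180)), spacing + 1e-9)
  expect_lt(abs(wrap_pi(b["theta2"] - 100 * pi / 180)), spacing + 1e-9)
})

test_that("transmural runs close single gaps, wrap zero, reject multifocal", {
  mk <- function(deg_on) {
    ang <- 2 * pi * (0:119) / 120
    data.frame(angle = ang, fraction = 1,
               transmural = (ang * 180 / pi) %in% deg_on, valid = TRUE)
  }
  expect_null(find_transmural_borders(mk(numeric(0))))
  run <- seq(40.5, 99.5, by = 3)  # not aligned; use indices instead
  ch <- mk(numeric(0))
  ch$transmural[14:34] <- TRUE
  b <- find_transmural_borders(ch)
  expect_equal(unname(b), c(ch$angle[14], ch$angle[34]))
  # one missing chord inside the run is closed
  ch$transmural[20] <- FALSE
  expect_equal(unname(find_transmural_borders(ch)),
               c(ch$angle[14], ch$angle[34]))
  # run wrapping through zero: 350 deg -> 20 deg has width 30 deg
  chw <- mk(numeric(0))
  chw$transmural[c(118:120, 1:7)] <- TRUE
  bw <- find_transmural_borders(chw)
  expect_equal(unname(wrap_2pi(bw["theta2"] - bw["theta1"])),
               9 * 2 * pi / 120, tolerance = 1e-9)
  # two disjoint wide runs are an error
  chm <- mk(numeric(0))
  chm$transmural[c(1:15, 60:75)] <- TRUE
  expect_error(find_transmural_borders(chm), "multi-focal")
})

test_that("segment models partition the circumference with correct classes", {
  # baseline: 6 equal healthy segments (mid), 4 (apical), anchored at ARVP
  base_mid <- build_segment_model(NULL, "mid")
  expect_equal(nrow(base_mid), 6)
  expect_true(all(base_mid$class == "healthy"))
  expect_equal(base_mid$theta1[1], 0)
  expect_equal(unique(round(wrap_2pi(base_mid$theta2 - base_mid$theta1), 10)),
               round(pi / 3, 10))
  expect_equal(nrow(build_segment_model(NULL, "apical")), 4)

  # post-MI mid slice with infarct [0, 60): five 60-degree arcs, the two
  # abutting arcs adjacent
  m <- build_segment_model(c(0, pi / 3), "mid")
  expect_equal(nrow(m), 6)
  expect_equal(m$class[1], "infarct")
  expect_equal(sum(m$class == "adjacent"), 2)
  expect_equal(sum(m$class == "remote"), 3)
  arcs <- wrap_2pi(m$theta2[-1] - m$theta1[-1])
  expect_equal(unique(round(arcs, 10)), round(pi / 3, 10))
  adj <- m[m$class == "adjacent", ]
  expect_equal(sort(round(c(adj$theta1, adj$theta2), 6)),
               sort(round(c(pi / 3, 2 * pi / 3, 2 * pi - pi / 3, 0), 6)))

  # apical slice with borders: one infarct + three arcs, 2 adjacent 1 remote
  a <- build_segment_model(c(0, pi / 3), "apical")
  expect_equal(nrow(a), 4)
  expect_equal(sum(a$class == "adjacent"), 2)
  expect_equal(sum(a$class == "remote"), 1)

  # partition: total angular coverage is exactly 2*pi for every model
  for (mod in list(base_mid, m, a)) {
    expect_equal(sum(wrap_2pi(mod$theta2 - mod$theta1) %% (2 * pi)), 2 * pi,
                 tolerance = 1e-9)
  }

  expect_error(build_segment_model(c(0, 310 * pi / 180), "mid"),
               "300 degrees")
})

test_that("slice levels split into thirds with the basal tie rule", {
  lev <- function(n) vapply(1:n, classify_slice_level, character(1),
                            n_slices = n)
  expect_equal(table(lev(9))[c("apical", "mid", "basal")],
               c(apical = 3L, mid = 3L, basal = 3L), ignore_attr = TRUE)
  expect_equal(table(lev(10))[c("apical", "mid", "basal")],
               c(apical = 3L, mid = 3L, basal = 4L), ignore_attr = TRUE)
  expect_equal(table(lev(12))[c("apical", "mid", "basal")],
               c(apical = 4L, mid = 4L, basal = 4L), ignore_attr = TRUE)
})

test_that("adjacency propagates to overlapping segments in neighbour slices", {
  m_inf <- build_segment_model(c(0, pi / 3), "mid", slice = 2)
  m_base <- build_segment_model(NULL, "mid", slice = 1)
  m_base3 <- build_segment_model(NULL, "mid", slice = 3)
  m_far <- build_segment_model(NULL, "mid", slice = 4)
  out <- propagate_adjacency(list(m_base, m_inf, m_base3, m_far))
  # slices 1 and 3 overlap the infarct interval [0, 60): their first healthy
  # segment becomes adjacent
  expect_equal(out[[1]]$class[1], "adjacent")
  expect_equal(out[[3]]$class[1], "adjacent")
  # slice 4 does not neighbour the infarct slice
  expect_true(all(out[[4]]$class == "healthy"))
  # no infarct anywhere: labels unchanged
  clean <- propagate_adjacency(list(m_base, m_base3))
  expect_true(all(clean[[1]]$class == "healthy"))

  # interior slices of a multi-slice infarct keep their own labels
  stack <- propagate_adjacency(list(
    build_segment_model(c(0, pi / 3), "mid", slice = 1),
    build_segment_model(c(0, pi / 3), "mid", slice = 2),
    build_segment_model(c(0, pi / 3), "mid", slice = 3)))
  expect_equal(stack[[2]]$class[1], "infarct")
})

test_that("affine registration round-trips and validates landmarks", {
  set.seed(14)
  from <- cbind(runif(12, -20, 20), runif(12, -20, 20))
  A <- matrix(c(0.95, 0.1, -0.08, 1.05), 2)
  b <- c(2, -3)
  to <- from %*% t(A) + matrix(b, 12, 2, byrow = TRUE)
  reg <- register_lge_to_tag(from, to)
  expect_lt(max(abs(reg$A - A)), 1e-6)
  expect_lt(max(abs(reg$b - b)), 1e-6)
  expect_lt(reg$rms, 1e-6)
  expect_lt(max(abs(reg$transform(from) - to)), 1e-6)

  # identical frames give the identity
  id <- register_lge_to_tag(from, from)
  expect_lt(max(abs(id$A - diag(2))), 1e-9)
  expect_lt(id$rms, 1e-6)

  col <- cbind(1:5, 2 * (1:5))
  expect_error(register_lge_to_tag(col, col), "collinear")

  # tagged slice at 24 mm pairs with the nearest 3 mm LGE slice
  lge_z <- seq(1.5, 76.5, by = 3)
  expect_equal(lge_z[pair_lge_slices(24, lge_z)], 24 - 1.5 + 1.5,
               tolerance = 1.5)
})
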