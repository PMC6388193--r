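# fit_assessment: margin images, indirect gap segmentation, thickness,
# statistics, ANOVA

test_that("measure_marginal_gap reads constructed edge separations", {
  # two parallel edges 10 px apart at 5 um/px -> six 50 um readings
  img <- matrix(0.05, 60, 40)
  img[1:20, ] <- 1.0
  img[30:49, ] <- 0.55
  m <- measure_marginal_gap(img, 5, "cervical")
  expect_length(m$readings, 6)
  expect_equal(unname(m$readings), rep(50, 6))

  # closed (zero-gap) margin: readings within one pixel of zero
  img0 <- matrix(0.05, 60, 40)
  img0[1:20, ] <- 1.0
  img0[21:40, ] <- 0.55
  m0 <- measure_marginal_gap(img0, 5, "mesial")
  expect_true(all(m0$readings <= 5))

  # single region -> detection error; short margin -> parameter error
  expect_error(measure_marginal_gap(matrix(1, 30, 30), 5, "distal"),
               "detection error")
  expect_error(measure_marginal_gap(img[, 1:4], 5, "distal",
                                    n_stations = 6),
               "parameter error")
})

test_that("station readings track a sinusoidal gap profile within a pixel", {
  px <- 5
  ncol <- 120
  # gentle slope: with shortest-distance semantics a steep profile reads
  # the tangent distance, not the per-column separation
  gap_px <- round(22 + 5 * sin(2 * pi * seq_len(ncol) / 120))
  img <- matrix(0.05, 80, ncol)
  for (cc in seq_len(ncol)) {
    img[1:20, cc] <- 1.0
    img[(20 + gap_px[cc]):min(20 + gap_px[cc] + 20, 80), cc] <- 0.55
  }
  m <- measure_marginal_gap(img, px, "cervical", n_stations = 6)
  stations <- round(seq(1, ncol, length.out = 6))
  # analytic shortest distance from the station's tooth-edge point to the
  # drawn veneer boundary curve
  analytic <- vapply(stations, function(cc)
    min(sqrt((seq_len(ncol) - cc)^2 + gap_px^2)) * px, 0)
  expect_true(all(abs(m$readings - analytic) <= px))
  # and the per-column profile itself is tracked closely
  expect_true(all(abs(m$readings - gap_px[stations] * px) <= 2 * px))
})

test_that("indirect gap segmentation recovers labelled phases", {
  sc <- enclosed_gap_scene(gap_um = 100)
  seg <- segment_gap_indirect(sc$volume, closing_radius = 0.2)
  gm <- reconstruct_gap_model(seg$combined, seg$enamel)
  truth <- sc$labels == which(sc$label_names == "air_gap")
  dice <- 2 * sum(truth & gm$mask$data) / (sum(truth) + sum(gm$mask$data))
  expect_gte(dice, 0.95)
  # voxel-level set identity
  expect_identical(gm$mask$data | !seg$combined$data | seg$enamel$data,
                   array(TRUE, dim(gm$mask$data)))

  # enamel mask == combined mask -> empty gap
  seg2 <- segment_gap_indirect(sc$volume, combined_threshold = c(0.3, Inf),
                               enamel_threshold = c(0.3, Inf),
                               closing_radius = 0)
  expect_false(any(seg2$gap$data))

  # Boolean algebra on toy masks: B inside A -> exactly A \ B
  fr <- list(spacing = rep(1, 3), origin = c(0, 0, 0))
  A <- array(FALSE, c(8, 8, 8)); A[2:7, 2:7, 2:7] <- TRUE
  B <- array(FALSE, c(8, 8, 8)); B[3:6, 3:6, 3:6] <- TRUE
  gm2 <- reconstruct_gap_model(binary_mask(A, fr), binary_mask(B, fr),
                               min_component = 1)
  expect_identical(gm2$mask$data, A & !B)
})

test_that("gap model reconstruction matches analytic shells", {
  s <- 0.0128
  n <- 71
  xs <- (seq_len(n) - 36) * s
  d <- c(n, n, n)
  X <- array(rep(xs, times = n * n), d)
  Y <- array(rep(rep(xs, each = n), times = n), d)
  Z <- array(rep(xs, each = n * n), d)
  rr <- sqrt(X^2 + Y^2 + Z^2)
  fr <- list(spacing = rep(s, 3), origin = rep(xs[1], 3))
  r1 <- 0.28; r2 <- 0.40
  combined <- binary_mask(rr < r2, fr)
  enamel <- binary_mask(rr < r1, fr)
  gm <- reconstruct_gap_model(combined, enamel)
  shell_vol <- 4 / 3 * pi * (r2^3 - r1^3)
  expect_equal(mask_volume_mm3(gm$mask), shell_vol, tolerance = 0.03)
  # dual-route consistency: mesh volume vs voxel volume within 5%
  expect_equal(mesh_volume(gm$mesh), mask_volume_mm3(gm$mask),
               tolerance = 0.05)

  # zero-gap phantom gives an empty model, not an error
  gm0 <- reconstruct_gap_model(enamel, enamel)
  expect_false(any(gm0$mask$data))
  expect_equal(nrow(gm0$mesh$faces), 0)
})

test_that("local thickness recovers slab and shell widths within a voxel", {
  s <- 0.0128
  fr <- list(spacing = rep(s, 3), origin = c(0, 0, 0))
  # slab of 100 um at 12.8 um voxels
  slab <- array(FALSE, c(24, 24, 30))
  slab[, , 10:17] <- TRUE    # 8 voxels = 102.4 um
  gm <- compute_thickness_map(
    structure(list(mask = binary_mask(slab, fr), thickness = numeric(0)),
              class = "gap_model"))
  expect_lte(abs(median(gm$thickness) - 102.4), s * 1000 + 1e-9)

  # spherical shell with outer - inner = 150 um
  n <- 71; xs <- (seq_len(n) - 36) * s
  d <- c(n, n, n)
  X <- array(rep(xs, times = n * n), d)
  Y <- array(rep(rep(xs, each = n), times = n), d)
  Z <- array(rep(xs, each = n * n), d)
  rr <- sqrt(X^2 + Y^2 + Z^2)
  shell <- rr < 0.35 & rr >= 0.20
  gms <- compute_thickness_map(
    structure(list(mask = binary_mask(array(shell, d), fr),
                   thickness = numeric(0)), class = "gap_model"))
  expect_lt(abs(median(gms$thickness) - 150), s * 1000)

  # single-voxel gap reads one voxel
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  g1 <- compute_thickness_map(
    structure(list(mask = binary_mask(one, fr), thickness = numeric(0)),
              class = "gap_model"))
  expect_equal(g1$thickness, s * 1000)
})

test_that("export_thickness_map writes STL plus a per-voxel CSV", {
  s <- 0.0128
  fr <- list(spacing = rep(s, 3), origin = c(0, 0, 0))
  slab <- array(FALSE, c(16, 16, 20)); slab[, , 8:12] <- TRUE
  shell_out <- array(FALSE, dim(slab)); shell_out[, , 6:14] <- TRUE
  gm <- reconstruct_gap_model(binary_mask(shell_out, fr),
                              binary_mask(shell_out & !slab, fr))
  gm <- compute_thickness_map(gm)
  stl <- file.path(tempdir(), "gap.stl")
  csv <- file.path(tempdir(), "gap.csv")
  export_thickness_map(gm, stl, csv)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), sum(gm$mask$data))
  expect_true(all(tab$thickness_um >= s * 1000))
  expect_true(is_watertight(read_mesh(stl)))
})

test_that("summarize_gap computes the documented statistics", {
  st <- summarize_gap(c(50, 100, 150))
  expect_equal(st$mean, 100)
  expect_equal(st$median, 100)
  expect_equal(st$fraction_below_cutoff, 1)
  expect_equal(unname(st$iqr), unname(quantile(c(50, 100, 150), c(0.25, 0.75))))
  expect_error(summarize_gap(numeric(0)), "parameter error")

  # scaling equivariance; fraction invariant under co-scaling
  set.seed(15)
  v <- rexp(200, 1 / 80)
  a <- summarize_gap(v, cutoff = 120)
  b <- summarize_gap(3 * v, cutoff = 360)
  expect_equal(b$mean, 3 * a$mean)
  expect_equal(b$sd, 3 * a$sd)
  expect_equal(unname(b$iqr), 3 * unname(a$iqr))
  expect_equal(b$fraction_below_cutoff, a$fraction_below_cutoff)

  # truncated-normal mean against the closed form (mu=100, sd=50, a=0)
  set.seed(99)
  mu <- 100; sg <- 50
  draws <- rnorm(20000, mu, sg)
  draws <- draws[draws > 0][1:1000]
  st2 <- summarize_gap(draws)
  alpha <- -mu / sg
  tn_mean <- mu + sg * dnorm(alpha) / (1 - pnorm(alpha))
  expect_lt(abs(st2$mean - tn_mean), 3 * st2$sd / sqrt(st2$n))
})

test_that("aggregate_per_sample_medians implements the average-median", {
  one <- aggregate_per_sample_medians(list(c(3, 9, 5)))
  expect_equal(one$mean, 5)
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)

  tri <- aggregate_per_sample_medians(list(c(100), c(150), c(200)))
  expect_equal(tri$mean, 150)

  set.seed(12)
  samples <- replicate(7, rnorm(11, 120, 30), simplify = FALSE)
  agg <- aggregate_per_sample_medians(samples)
  med <- vapply(samples, median, 0)
  expect_equal(agg$mean, mean(med))
  expect_equal(agg$sd, sd(med))
  expect_error(aggregate_per_sample_medians(list()), "parameter error")
})

test_that("one_way_anova matches sums of squares and the t^2 identity", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)

  # brute force: SSB = 4 (df 2), SSW = 1.5 (df 3) -> F = 4
  res <- one_way_anova(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(res$f_statistic, 4)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 3L)

  # two groups: F equals the square of the pooled t statistic
  set.seed(33)
  g1 <- rnorm(9, 0, 1); g2 <- rnorm(12, 0.7, 1)
  f2 <- one_way_anova(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(f2$f_statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f2$p_value, tt$p.value, tolerance = 1e-12)

  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(c(1, 2))), "parameter error")
  expect_error(one_way_anova(list(c(1, 2), c(3))), "parameter error")
})

test_that("one_way_anova equals an independent lm/anova oracle (property)", {
  set.seed(77)
  for (trial in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:9, 1), i * 0.3, 1))
    got <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_len(k), lengths(groups))))
    ref <- anova(lm(y ~ g, data = df))
    expect_equal(got$f_statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})
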