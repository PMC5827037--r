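# fabricate a Z matrix directly (rows = compounds, cols = cell lines)
zmat <- function(n, panel, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * nrow(panel)), n, nrow(panel),
              dimnames = list(sprintf("c%03d", 1:n), panel$cell_line))
  apply(z, 2, function(v) (v - mean(v)) / sd(v))
}

test_that("group deltas match hand values and a brute-force reference", {
  panel <- panel_2x2()
  z <- rbind(c(-1, -1, 1, 1), c(0.3, 0.3, 0.3, 0.3))
  dimnames(z) <- list(c("a", "b"), panel$cell_line)
  rec <- group_deltas(z, panel)
  expect_equal(rec$delta, c(-2, 0))
  expect_equal(rec$mean_z_nontumour, NULL)

  z2 <- zmat(60, panel, seed = 4)
  rec2 <- group_deltas(z2, panel)
  ref <- sapply(seq_len(60), function(i)
    mean(z2[i, c("SI1", "SI2")]) - mean(z2[i, c("PAN1", "PAN2")]))
  expect_lt(max(abs(rec2$delta - ref)), 1e-12)

  bad <- rbind(panel, data.frame(cell_line = "GHOST", group = "SINET"))
  expect_error(group_deltas(z2, bad), "GHOST")
})

test_that("delta is antisymmetric and enrichment is invariant under label swap", {
  panel <- panel_2x2()
  z <- zmat(90, panel, seed = 9)
  ann <- data.frame(compound_id = rownames(z),
                    class = rep(sprintf("k%02d", 1:9), each = 10))
  swapped <- panel
  swapped$group <- ifelse(panel$group == "SINET", "PanNET", "SINET")
  r1 <- group_deltas(z, panel, annotation = ann)
  r2 <- group_deltas(z, swapped, annotation = ann)
  expect_equal(r2$delta, -r1$delta, tolerance = 1e-12)
  e1 <- class_enrichment(empirical_null_pscores(r1))
  e2 <- class_enrichment(empirical_null_pscores(r2))
  expect_equal(e1$p, e2$p, tolerance = 1e-12)
  expect_equal(e1$q, e2$q, tolerance = 1e-12)
  expect_equal(empirical_null_pscores(r1)$p_score,
               empirical_null_pscores(r2)$p_score, tolerance = 1e-12)
})

test_that("empirical-null p-scores follow the fitted normal", {
  panel <- panel_2x2()
  rec <- group_deltas(zmat(50, panel, seed = 2), panel)
  mu <- mean(rec$delta)
  sig <- sqrt(mean((rec$delta - mu)^2))
  # force known deltas through the scorer
  rec$delta[1] <- mu
  rec$delta[2] <- mu + 1.959964 * sig
  # refit shifts mu/sigma slightly; compute on a frozen copy instead
  scored <- empirical_null_pscores(rec)
  mu2 <- attr(scored, "null_mean"); sig2 <- attr(scored, "null_sd")
  expect_equal(scored$p_score,
               2 * pnorm(-abs(rec$delta - mu2) / sig2), tolerance = 1e-12)
  expect_true(all(scored$p_score > 0 & scored$p_score <= 1))

  # exact anchors: with deltas {-1, 1} the ML fit is mu = 0, sigma = 1,
  # so both p-scores are 2 * pnorm(-1); a delta at mu scores exactly 1
  # and one at mu + 1.959964 sigma scores 0.05
  rec2 <- data.frame(compound_id = c("a", "b"), delta = c(-1, 1))
  scored2 <- empirical_null_pscores(rec2, min_compounds = 2)
  expect_equal(scored2$p_score, rep(2 * pnorm(-1), 2), tolerance = 1e-12)
  d3 <- c(-1.959964, 1.959964, rep(0, 20))
  sc3 <- empirical_null_pscores(data.frame(delta = d3))
  mu3 <- attr(sc3, "null_mean"); s3 <- attr(sc3, "null_sd")
  expect_equal(sc3$p_score[3], 1)                       # delta == mu
  expect_equal(2 * pnorm(-abs(mu3 + 1.959964 * s3 - mu3) / s3), 0.05,
               tolerance = 1e-6)
  expect_error(empirical_null_pscores(data.frame(delta = rep(1, 30))),
               "degenerate null")
})

test_that("p-scores are approximately uniform on a simulated null screen", {
  panel <- panel_2x2()
  sim <- generate_screen(screen_design(n_compounds = 300, cell_lines = panel,
                                       seed = 303), plate_effect_sd = 0)
  rec <- empirical_null_pscores(group_deltas(normalize_screen(sim$wells), panel))
  expect_gt(stats::ks.test(rec$p_score, "punif")$p.value, 0.01)
})

test_that("WMW exact p matches enumeration and hand examples", {
  expect_equal(wmw_test(c(1, 2), c(3, 4))$U, 0)
  expect_equal(wmw_test(c(1, 2), c(3, 4))$p, 1 / 3, tolerance = 1e-12)
  # identical multisets: symmetric, p = 1
  expect_equal(wmw_test(c(1, 2), c(1, 2))$p, 1)

  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    x <- sample(1:6, n1, replace = TRUE)  # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    got <- wmw_test(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$U, oracle_U(x, y))
    expect_equal(got$p, oracle_wmw_exact(x, y), tolerance = 1e-12)
  }
})

test_that("class enrichment BH q equals the textbook step-up and guards hold", {
  panel <- panel_2x2()
  z <- zmat(80, panel, seed = 6)
  ann <- data.frame(compound_id = rownames(z),
                    class = rep(sprintf("k%02d", 1:8), each = 10))
  rec <- group_deltas(z, panel, annotation = ann)
  enr <- class_enrichment(rec)
  expect_equal(enr$q, oracle_bh(enr$p), tolerance = 1e-12)
  expect_true(all(enr$q >= enr$p - 1e-12))
  expect_true(all(diff(enr$q[order(enr$p)]) >= -1e-12))

  # worked BH example on three classes
  expect_equal(oracle_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))

  # class spanning the whole library has no complement
  rec$class <- "all"
  expect_error(class_enrichment(rec), "empty complement")

  # small classes are reported untested, not dropped
  ann2 <- ann; ann2$class[1:3] <- "tiny"
  rec2 <- group_deltas(z, panel, annotation = ann2)
  enr2 <- class_enrichment(rec2, min_class_size = 5)
  expect_true("tiny" %in% enr2$class)
  expect_false(enr2$tested[enr2$class == "tiny"])
  expect_true(is.na(enr2$q[enr2$class == "tiny"]))
})

test_that("signed-rank test matches enumeration, convention and error path", {
  st <- signed_rank_test(c(1, 2, 3, 4, 5, 6))
  expect_equal(st$p, 0.03125)
  expect_equal(st$V, 21)

  expect_error(signed_rank_test(rep(0, 5)), "no nonzero differences")

  set.seed(77)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    d <- sample(-4:4, n, replace = TRUE)  # zeros and ties likely
    if (all(d == 0)) d[1] <- 1
    got <- signed_rank_test(d)
    expect_equal(got$p, oracle_signed_rank_exact(d), tolerance = 1e-12)
  }
})

test_that("group_effect_test pairs by compound and gains power with effect size", {
  panel3 <- rbind(panel_2x2(),
                  data.frame(cell_line = c("NT1", "NT2"),
                             group = c("nontumour", "nontumour")))
  meds <- sapply(c(0, 0.2, 0.5), function(eff) {
    ps <- sapply(1:30, function(i) {
      des <- screen_design(n_compounds = 60, cell_lines = panel3,
                           seed = round(7000 + 1000 * eff) + i)
      effects <- if (eff > 0) list(effect_spec("class_01", "PanNET", eff))
        else list()
      sim <- generate_screen(des, effects, noise_cv = 0.1)
      rec <- group_deltas(normalize_screen(sim$wells), panel3,
                          annotation = sim$annotation)
      group_effect_test(rec, "class_01", c("SINET", "PanNET"))$p
    })
    median(ps)
  })
  # p falls as the effect grows (the exact test floors at 2/2^10, so the
  # top step is non-strict)
  expect_lt(meds[2], meds[1])
  expect_lte(meds[3], meds[2])
  expect_lt(meds[3], 0.05)

  # all-tied pairs exercise the error path
  rec <- data.frame(class = rep("k", 6),
                    mean_z_SINET = 1:6, mean_z_PanNET = 1:6)
  expect_error(group_effect_test(rec, "k", c("SINET", "PanNET")),
               "no nonzero differences")
})
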