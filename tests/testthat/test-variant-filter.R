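vr <- function(class = "snp", QD = 20, MQ = 55, FS = 5,
               ReadPosRankSum = 0, MQRankSum = 0, maf = NA,
               consequence = "missense", chrom = "chr1", pos = 100L,
               ref = "A", alt = "T", zygosity = "het") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             variant_class = class, QD = QD, MQ = MQ, FS = FS,
             ReadPosRankSum = ReadPosRankSum, MQRankSum = MQRankSum,
             zygosity = zygosity, maf = maf, consequence = consequence,
             stringsAsFactors = FALSE)
}

test_that("hard filters apply strict printed thresholds per variant class", {
  expect_identical(apply_hard_filters(vr(QD = 1.9))$failed_filters, "QD<2")
  # boundary-equal values PASS (inequalities are strict)
  bdry <- vr(QD = 2.0, MQ = 40.0, FS = 60.0,
             ReadPosRankSum = -8.0, MQRankSum = -12.5)
  expect_true(apply_hard_filters(bdry)$filter_pass)

  # a failing record collects every failed rule name
  worst <- apply_hard_filters(vr(QD = 0.5, MQ = 10, FS = 100,
                                 ReadPosRankSum = -9, MQRankSum = -20))
  expect_identical(worst$failed_filters,
                   "QD<2;MQ<40;FS>60;ReadPosRankSum<-8;MQRankSum<-12.5")

  # indels are never judged by SNP thresholds: FS 100 passes, MQ ignored
  ind <- apply_hard_filters(vr(class = "indel", FS = 100, MQ = 5,
                               ReadPosRankSum = -15))
  expect_true(ind$filter_pass)
  expect_false(apply_hard_filters(vr(class = "indel", FS = 201))$filter_pass)

  # missing annotations never fail their filter
  miss <- vr(); miss$ReadPosRankSum <- NA; miss$MQRankSum <- NA
  expect_true(apply_hard_filters(miss)$filter_pass)

  expect_error(apply_hard_filters(vr(class = "sv")), "unknown variant class")
  expect_identical(apply_hard_filters(vr(class = "SNP", QD = 1))$failed_filters,
                   "QD<2")
})

test_that("MAF filter removes common variants with configurable boundary", {
  tab <- do.call(rbind, list(vr(maf = 0.02), vr(maf = 0.01), vr(maf = 0.005),
                             vr(maf = NA)))
  kept <- maf_filter(tab)
  expect_equal(kept$maf, c(0.01, 0.005, NA))     # > 0.01 removed, 0.01 kept
  expect_equal(attr(kept, "n_no_maf"), 1L)
  strict <- maf_filter(tab, boundary = "remove")
  expect_equal(strict$maf, c(0.005, NA))

  set.seed(12)
  big <- vr()[rep(1, 500), ]
  big$maf <- ifelse(runif(500) < 0.3, NA, runif(500, 0, 0.05))
  expect_equal(nrow(maf_filter(big)),
               sum(is.na(big$maf) | big$maf <= 0.01))
})

test_that("consequence filter keeps protein-altering classes and uses the toy gene model", {
  expect_equal(nrow(consequence_filter(vr(consequence = "synonymous"))), 0L)
  expect_equal(nrow(consequence_filter(vr(consequence = "missense"))), 1L)

  gm <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(100L, 500L, 0L), end = c(200L, 600L, 50L),
                   frame = c(0L, 1L, 0L))
  # enumerated fixture: position/class -> retained?
  cases <- rbind(
    vr(chrom = "chr1", pos = 150, ref = "AT", alt = "A", class = "indel",
       consequence = NA),                      # exonic 1-bp del: frameshift
    vr(chrom = "chr1", pos = 150, ref = "ATTT", alt = "A", class = "indel",
       consequence = NA),                      # 3-bp del: nonframeshift
    vr(chrom = "chr1", pos = 300, ref = "AT", alt = "A", class = "indel",
       consequence = NA),                      # intronic indel: removed
    vr(chrom = "chr1", pos = 150, consequence = NA),  # exonic SNP, unknown
    vr(chrom = "chr9", pos = 10, consequence = NA))   # contig not in model
  kept <- consequence_filter(cases, gene_model = gm)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$ref, c("AT", "ATTT"))
  expect_equal(attr(kept, "n_unclassified"), 1L)
  expect_equal(attr(kept, "n_no_contig"), 1L)

  expect_error(consequence_filter(vr(consequence = NA)), "gene_model")
})

test_that("funnel counts match a brute-force recount and stay monotone", {
  sim <- generate_variants(variant_sim_spec(n_snps = 2000, n_indels = 500,
                                            seed = 41))
  fun <- variant_funnel(sim$records)
  tr <- sim$truth
  for (cl in c("snp", "indel")) {
    sel <- tr$variant_class == cl
    pa <- sim$records$consequence %in% protein_altering_classes()
    expected <- c(sum(sel),
                  sum(sel & tr$quality_pass),
                  sum(sel & tr$quality_pass & tr$maf_retained),
                  sum(sel & tr$quality_pass & tr$maf_retained & pa))
    expect_equal(fun$n[fun$variant_class == cl], expected)
    expect_equal(fun$pct_of_detected[fun$variant_class == cl],
                 100 * expected / expected[1])
    expect_true(all(diff(fun$n[fun$variant_class == cl]) <= 0))
  }

  empty <- variant_funnel(sim$records[0, ])
  expect_equal(empty$n, rep(0L, 8))

  clean <- generate_variants(variant_sim_spec(
    n_snps = 100, n_indels = 20,
    fail_fractions = list(snp = c(QD = 0), indel = c(QD = 0)),
    maf_present = 0, frac_protein_altering = 1, seed = 2))
  fc <- variant_funnel(clean$records)
  expect_true(all(tapply(fc$n, fc$variant_class, function(v) all(v == v[1]))))
})

test_that("funnel monotonicity holds over random simulator specs", {
  set.seed(99)
  for (i in 1:10) {
    spec <- variant_sim_spec(
      n_snps = sample(50:300, 1), n_indels = sample(10:100, 1),
      fail_fractions = list(
        snp = c(QD = runif(1, 0, 0.5), MQ = runif(1, 0, 0.5),
                FS = runif(1, 0, 0.5)),
        indel = c(QD = runif(1, 0, 0.5), FS = runif(1, 0, 0.5))),
      maf_present = runif(1), frac_protein_altering = runif(1),
      seed = 900 + i)
    fun <- variant_funnel(generate_variants(spec)$records)
    for (cl in unique(fun$variant_class))
      expect_true(all(diff(fun$n[fun$variant_class == cl]) <= 0))
  }
})

test_that("verdicts are order-invariant", {
  sim <- generate_variants(variant_sim_spec(n_snps = 200, n_indels = 50,
                                            seed = 8))
  set.seed(3)
  perm <- sample(nrow(sim$records))
  a <- apply_hard_filters(sim$records)[perm, ]
  b <- apply_hard_filters(sim$records[perm, ])
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("bi-allelic inactivation logic matches its truth table", {
  grid <- expand.grid(mutation = c("none", "het", "hom"),
                      copy = c("normal", "single-copy", "homozygous loss",
                               "amplification"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    m <- grid$mutation[i]; cc <- grid$copy[i]
    expected <- (m == "hom" && cc != "homozygous loss") ||
      (m == "het" && cc == "single-copy") || (cc == "homozygous loss")
    ev <- if (m == "hom" && cc == "homozygous loss")
      suppressWarnings(biallelic_call("G", m, cc)) else biallelic_call("G", m, cc)
    expect_identical(ev$biallelic, expected,
                     label = sprintf("mutation=%s copy=%s", m, cc))
  }
  expect_warning(biallelic_call("ATRX", "hom", "homozygous loss"),
                 "contradictory")
})

test_that("VCF round-trip preserves the flat table through VariantAnnotation", {
  skip_if_not_installed("VariantAnnotation")
  sim <- generate_variants(variant_sim_spec(n_snps = 150, n_indels = 40,
                                            seed = 14))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(sim$records, f)
  back <- read_variant_vcf(f)
  expect_equal(nrow(back), nrow(sim$records))
  expect_identical(back$variant_class, sim$records$variant_class)
  expect_identical(back$zygosity, sim$records$zygosity)
  expect_identical(back$consequence, sim$records$consequence)
  expect_equal(back$maf, sim$records$maf, tolerance = 1e-5)
  expect_equal(back$QD, sim$records$QD, tolerance = 1e-5)
  # verdicts identical through the round trip
  expect_identical(apply_hard_filters(back)$failed_filters,
                   apply_hard_filters(sim$records)$failed_filters)
})
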