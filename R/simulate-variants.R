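## Synthetic called-variant tables with per-record ground truth.
##
## Annotation values are drawn on the passing or failing side of each
## hard-filter threshold according to per-filter failure fractions, so
## the emitted truth labels are consistent with the emitted values by
## construction (and re-derivable by any independent rule
## implementation).

#' Describe a synthetic variant table
#'
#' @param n_snps,n_indels record counts per class.
#' @param fail_fractions named list `snp`, `indel` of per-annotation
#'   failure probabilities (names as in [hard_filter_rules()]).  Missing
#'   entries default to 0.
#' @param maf_present probability that a record carries a population
#'   MAF (absent = novel, treated as rare downstream).
#' @param maf_shape1,maf_shape2 Beta parameters of the MAF values; the
#'   defaults put most mass near zero with a realistic common-variant
#'   tail.
#' @param frac_protein_altering fraction of records whose consequence
#'   class is exonic protein-altering.
#' @param het_fraction heterozygous fraction of the zygosity mix.
#' @param missing_ranksum probability that a rank-sum annotation is
#'   absent (missing values never fail a filter).
#' @param seed integer seed.
#' @return object of class `variant_sim_spec`.
#' @export
variant_sim_spec <- function(n_snps = 1000L, n_indels = 200L,
                             fail_fractions = list(
                               snp = c(QD = 0.03, MQ = 0.02, FS = 0.02,
                                       ReadPosRankSum = 0.01, MQRankSum = 0.01),
                               indel = c(QD = 0.05, FS = 0.02,
                                         ReadPosRankSum = 0.02)),
                             maf_present = 0.7,
                             maf_shape1 = 0.3, maf_shape2 = 2,
                             frac_protein_altering = 0.1,
                             het_fraction = 0.7,
                             missing_ranksum = 0.05,
                             seed = 1L) {
  assert_that(is_count(n_snps + 1) && is_count(n_indels + 1),
              "record counts must be non-negative integers")
  for (cls in names(fail_fractions))
    assert_that(is_prob(fail_fractions[[cls]]),
                "failure fractions for %s must be in [0, 1]", cls)
  assert_that(is_prob(c(maf_present, frac_protein_altering, het_fraction,
                        missing_ranksum)),
              "probabilities must be in [0, 1]")
  structure(list(n_snps = as.integer(n_snps), n_indels = as.integer(n_indels),
                 fail_fractions = fail_fractions, maf_present = maf_present,
                 maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
                 frac_protein_altering = frac_protein_altering,
                 het_fraction = het_fraction,
                 missing_ranksum = missing_ranksum, seed = as.integer(seed)),
            class = "variant_sim_spec")
}

## passing / failing value ranges per annotation (open intervals strictly
## inside / outside each threshold)
annot_value <- function(n, key, cls, fail) {
  rng <- switch(paste(cls, key),
    "snp QD" = list(pass = c(2, 35), fail = c(0.1, 2)),
    "snp MQ" = list(pass = c(40, 60), fail = c(10, 40)),
    "snp FS" = list(pass = c(0, 60), fail = c(60, 250)),
    "snp ReadPosRankSum" = list(pass = c(-8, 8), fail = c(-20, -8)),
    "snp MQRankSum" = list(pass = c(-12.5, 12.5), fail = c(-25, -12.5)),
    "indel QD" = list(pass = c(2, 35), fail = c(0.1, 2)),
    "indel FS" = list(pass = c(0, 200), fail = c(200, 500)),
    "indel ReadPosRankSum" = list(pass = c(-20, 10), fail = c(-40, -20)),
    stopf("no value model for %s/%s", cls, key))
  fail <- rep(fail, length.out = n)
  lo <- ifelse(fail, rng$fail[1L], rng$pass[1L])
  hi <- ifelse(fail, rng$fail[2L], rng$pass[2L])
  runif(n, lo, hi)
}

#' Simulate a called-variant table with ground truth
#'
#' @param spec a [variant_sim_spec()].
#' @return list of class `variant_sim`: `records` (flat table with
#'   columns chrom, pos, ref, alt, variant_class, QD, MQ, FS,
#'   ReadPosRankSum, MQRankSum, zygosity, maf, consequence) and `truth`
#'   (per record: the filters it fails, `quality_pass`, `maf_retained`,
#'   `protein_altering`).
#' @export
generate_variants <- function(spec) {
  assert_that(inherits(spec, "variant_sim_spec"), "spec must be a variant_sim_spec")
  rules <- hard_filter_rules()
  with_seed(spec$seed, {
    make_class <- function(cls, n) {
      if (!n) return(NULL)
      rt <- rules[[cls]]
      rec <- data.frame(
        chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
        pos = sample.int(5e7, n, replace = TRUE),
        stringsAsFactors = FALSE)
      bases <- c("A", "C", "G", "T")
      if (cls == "snp") {
        rec$ref <- sample(bases, n, replace = TRUE)
        shift <- sample(1:3, n, replace = TRUE)
        rec$alt <- bases[(match(rec$ref, bases) + shift - 1L) %% 4L + 1L]
      } else {
        ins <- runif(n) < 0.5
        len <- sample(1:6, n, replace = TRUE)
        extra <- vapply(len, function(k)
          paste(sample(bases, k, replace = TRUE), collapse = ""), character(1))
        anchor <- sample(bases, n, replace = TRUE)
        rec$ref <- ifelse(ins, anchor, paste0(anchor, extra))
        rec$alt <- ifelse(ins, paste0(anchor, extra), anchor)
      }
      rec$variant_class <- cls
      fails <- matrix(FALSE, n, nrow(rt),
                      dimnames = list(NULL, rt$annotation))
      for (i in seq_len(nrow(rt))) {
        key <- rt$annotation[i]
        frac <- spec$fail_fractions[[cls]][key]
        if (is.na(frac) || is.null(frac)) frac <- 0
        fail <- runif(n) < frac
        v <- annot_value(n, key, cls, fail)
        if (key %in% c("ReadPosRankSum", "MQRankSum")) {
          gone <- runif(n) < spec$missing_ranksum
          v[gone] <- NA_real_
          fail[gone] <- FALSE
        }
        rec[[key]] <- v
        fails[, i] <- fail
      }
      for (key in setdiff(c("QD", "MQ", "FS", "ReadPosRankSum", "MQRankSum"),
                          rt$annotation))
        rec[[key]] <- NA_real_
      rec$zygosity <- ifelse(runif(n) < spec$het_fraction, "het", "hom")
      has_maf <- runif(n) < spec$maf_present
      maf <- rbeta(n, spec$maf_shape1, spec$maf_shape2) / 2
      rec$maf <- ifelse(has_maf, maf, NA_real_)
      pa <- runif(n) < spec$frac_protein_altering
      pa_classes <- if (cls == "snp") c("missense", "nonsense", "stoploss")
        else c("frameshift", "nonframeshift")
      other <- c("synonymous", "non-exonic", "UTR", "intronic")
      rec$consequence <- ifelse(pa,
                                sample(pa_classes, n, replace = TRUE),
                                sample(other, n, replace = TRUE))
      failed_names <- apply(fails, 1L, function(f)
        paste(sprintf("%s%s%g", rt$annotation[f],
                      ifelse(rt$direction[f] == "lt", "<", ">"),
                      rt$cut[f]), collapse = ";"))
      truth <- data.frame(
        variant_class = cls,
        failed_filters = failed_names,
        quality_pass = !apply(fails, 1L, any),
        maf_retained = is.na(rec$maf) | rec$maf <= 0.01,
        protein_altering = pa,
        stringsAsFactors = FALSE)
      list(rec = rec, truth = truth)
    }
    parts <- Filter(Negate(is.null),
                    list(make_class("snp", spec$n_snps),
                         make_class("indel", spec$n_indels)))
    rec <- do.call(rbind, lapply(parts, `[[`, "rec"))
    truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
    rownames(rec) <- rownames(truth) <- NULL
    structure(list(records = rec, truth = truth, spec = spec),
              class = "variant_sim")
  })
}

#' Write a variant table as minimal VCF 4.2
#'
#' Emits a small, self-contained VCF: one sample, `GT` genotype, INFO
#' keys `QD`, `MQ`, `FS`, `ReadPosRankSum`, `MQRankSum`, `AF_POP`
#' (population MAF) and `CSQCLASS` (consequence class).  The file is
#' plain text and byte-deterministic for a fixed table.
#'
#' @param records flat variant table (see [generate_variants()]).
#' @param path output file.
#' @param sample sample name.
#' @export
write_variant_vcf <- function(records, path, sample = "SAMPLE") {
  num_info <- c("QD", "MQ", "FS", "ReadPosRankSum", "MQRankSum")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=netscreen",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            c(num_info, "AF_POP"),
            c("Quality by depth", "RMS mapping quality",
              "Fisher strand bias (phred)",
              "Read position rank-sum", "Mapping quality rank-sum",
              "Population minor allele frequency")),
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  fmt1 <- function(key, v) ifelse(is.na(v), NA_character_,
                                  sprintf("%s=%s", key, formatC(v, digits = 6,
                                                                format = "g")))
  info_cols <- cbind(
    do.call(cbind, lapply(num_info, function(k)
      fmt1(k, if (k %in% names(records)) records[[k]] else
        rep(NA_real_, nrow(records))))),
    fmt1("AF_POP", records$maf),
    ifelse(is.na(records$consequence), NA_character_,
           paste0("CSQCLASS=", records$consequence)))
  info <- apply(info_cols, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else "."
  })
  gt <- ifelse(records$zygosity == "hom", "1/1", "0/1")
  body <- paste(sub("^chr", "", records$chrom), records$pos, ".",
                records$ref, records$alt, ".", ".", info, "GT", gt,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF 4.2 variant table
#'
#' Uses Bioconductor's VariantAnnotation parser when available (the
#' normal case) and maps the result back onto the flat-table layout used
#' throughout this package.  Multi-allelic records are split per ALT
#' allele before filtering.
#'
#' @param path VCF file (plain text).
#' @return flat variant table as produced by [generate_variants()].
#' @export
read_variant_vcf <- function(path) {
  assert_that(requireNamespace("VariantAnnotation", quietly = TRUE),
              "reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  vcf <- VariantAnnotation::expand(vcf)  # split multi-allelic records
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  getn <- function(k) if (k %in% names(info)) as.numeric(info[[k]]) else
    rep(NA_real_, length(rr))
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  gtm <- VariantAnnotation::geno(vcf)$GT
  gt <- if (!is.null(gtm)) gtm[, 1L] else rep("0/1", length(rr))
  csq <- if ("CSQCLASS" %in% names(info))
    as.character(info$CSQCLASS) else rep(NA_character_, length(rr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt,
    variant_class = ifelse(nchar(ref) == 1L & nchar(alt) == 1L,
                           "snp", "indel"),
    QD = getn("QD"), MQ = getn("MQ"), FS = getn("FS"),
    ReadPosRankSum = getn("ReadPosRankSum"), MQRankSum = getn("MQRankSum"),
    zygosity = ifelse(gt %in% c("1/1", "1|1"), "hom", "het"),
    maf = getn("AF_POP"),
    consequence = csq,
    stringsAsFactors = FALSE, row.names = NULL)
}
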