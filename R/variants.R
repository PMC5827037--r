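## Post-calling variant cascade: GATK-style hard filters, population
## allele-frequency filter, protein-altering consequence filter, funnel
## accounting, and the gene-level bi-allelic-inactivation call.
##
## Hard-filter thresholds (all inequalities strict; a missing annotation
## never fails its filter):
##   SNPs:   QD < 2.0, MQ < 40.0, FS > 60.0, ReadPosRankSum < -8.0,
##           MQRankSum < -12.5
##   indels: QD < 2.0, FS > 200.0, ReadPosRankSum < -20.0

#' Default hard-filter rule tables
#'
#' One row per rule: annotation key, direction (`lt` fails when the value
#' is strictly below the cut, `gt` strictly above) and the cut.
#' @return named list with elements `snp` and `indel`.
#' @export
hard_filter_rules <- function() {
  list(
    snp = data.frame(
      annotation = c("QD", "MQ", "FS", "ReadPosRankSum", "MQRankSum"),
      direction = c("lt", "lt", "gt", "lt", "lt"),
      cut = c(2.0, 40.0, 60.0, -8.0, -12.5),
      stringsAsFactors = FALSE),
    indel = data.frame(
      annotation = c("QD", "FS", "ReadPosRankSum"),
      direction = c("lt", "gt", "lt"),
      cut = c(2.0, 200.0, -20.0),
      stringsAsFactors = FALSE))
}

#' Apply quality hard filters to called variants
#'
#' Each record is evaluated against the rule set of its variant class
#' (SNP rules never touch indels and vice versa).  A record fails a rule
#' iff its annotation value satisfies the rule's strict inequality;
#' boundary-equal values pass.  The verdict is a pure per-record
#' function: record order is irrelevant.
#'
#' @param records data.frame with columns `variant_class`
#'   (`"SNP"`/`"indel"`) and the annotation columns named in `rules`
#'   (missing columns or NA values never fail).
#' @param rules rule tables as from [hard_filter_rules()].
#' @return `records` with columns `filter_pass` (logical) and
#'   `failed_filters` (`;`-separated rule names such as `"QD<2"`, empty
#'   string when PASS).
#' @export
apply_hard_filters <- function(records, rules = hard_filter_rules()) {
  assert_that(is.data.frame(records) && "variant_class" %in% names(records),
              "records need a variant_class column")
  records$variant_class <- tolower(records$variant_class)  # "SNP" == "snp"
  bad <- setdiff(unique(records$variant_class), names(rules))
  if (length(bad)) stopf("unknown variant class '%s'", bad[1L])
  failed <- rep("", nrow(records))
  for (cls in names(rules)) {
    sel <- records$variant_class == cls
    if (!any(sel)) next
    rt <- rules[[cls]]
    for (i in seq_len(nrow(rt))) {
      key <- rt$annotation[i]
      if (!key %in% names(records)) next
      v <- records[[key]][sel]
      hit <- if (rt$direction[i] == "lt") v < rt$cut[i] else v > rt$cut[i]
      hit[is.na(hit)] <- FALSE  # missing annotation does not fail
      name <- sprintf("%s%s%g", key, if (rt$direction[i] == "lt") "<" else ">",
                      rt$cut[i])
      idx <- which(sel)[hit]
      failed[idx] <- ifelse(failed[idx] == "", name,
                            paste(failed[idx], name, sep = ";"))
    }
  }
  records$failed_filters <- failed
  records$filter_pass <- failed == ""
  records
}

#' Population allele-frequency filter
#'
#' Removes common polymorphisms: records with population MAF strictly
#' above `threshold` are dropped.  Records without a MAF entry are kept
#' (treated as rare).  The original analysis removed `MAF > 0.01`; a
#' stricter reading (`>=`, dropping exactly-0.01 variants) is available
#' via `boundary = "remove"`.
#'
#' @param records data.frame with a `maf` column (NA = absent).
#' @param threshold MAF cut in `[0, 1]`.
#' @param boundary `"retain"` (default, strict `>`) or `"remove"` (`>=`).
#' @return records retained, with attribute `n_no_maf` counting retained
#'   records that had no MAF entry.
#' @export
maf_filter <- function(records, threshold = 0.01,
                       boundary = c("retain", "remove")) {
  boundary <- match.arg(boundary)
  assert_that(is_prob(threshold) && length(threshold) == 1L,
              "threshold must be in [0, 1]")
  maf <- records$maf
  drop <- if (boundary == "retain") maf > threshold else maf >= threshold
  drop[is.na(drop)] <- FALSE
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_no_maf") <- sum(is.na(maf[!drop]))
  out
}

#' Default set of protein-altering consequence classes
#' @export
protein_altering_classes <- function() {
  c("missense", "nonsense", "stoploss",
    "frameshift", "nonframeshift")
}

#' Retain exonic protein-altering variants
#'
#' Keeps records whose consequence class is in `retain` (missense,
#' nonsense, stop-loss, frameshift and non-frameshift coding changes by
#' default); synonymous and non-exonic records are removed.  When a
#' record has no `consequence` annotation it is classified against a toy
#' gene model: outside every exon -> non-exonic; an exonic indel is
#' frameshift/nonframeshift by length modulo 3; an exonic SNP without
#' annotation cannot be split into missense vs synonymous and is removed
#' (conservative), logged via the `n_unclassified` attribute.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class` and optionally `consequence`.
#' @param gene_model optional data.frame of exon intervals: `chrom`,
#'   `start`, `end` (0-based half-open), `frame`.
#' @param retain consequence classes to keep.
#' @return retained records; attributes `n_unclassified` and
#'   `n_no_contig` (records on contigs absent from the gene model).
#' @export
consequence_filter <- function(records, gene_model = NULL,
                               retain = protein_altering_classes()) {
  csq <- if ("consequence" %in% names(records)) records$consequence else
    rep(NA_character_, nrow(records))
  n_no_contig <- 0L
  need <- which(is.na(csq))
  if (length(need)) {
    assert_that(!is.null(gene_model),
                "records without consequence annotation need a gene_model")
    assert_that(all(c("chrom", "start", "end") %in% names(gene_model)),
                "gene_model needs chrom, start, end")
    lv <- union(gene_model$chrom, records$chrom[need])
    gr_ex <- GenomicRanges::GRanges(
      factor(gene_model$chrom, lv),
      IRanges::IRanges(gene_model$start + 1L, gene_model$end))
    known <- records$chrom[need] %in% gene_model$chrom
    n_no_contig <- sum(!known)
    gr_v <- GenomicRanges::GRanges(
      factor(records$chrom[need], lv),
      IRanges::IRanges(records$pos[need], records$pos[need]))
    inexon <- IRanges::overlapsAny(gr_v, gr_ex) & known
    cls <- records$variant_class[need]
    indel_len <- abs(nchar(records$ref[need]) - nchar(records$alt[need]))
    csq[need] <- ifelse(!inexon, "non-exonic",
                 ifelse(cls == "indel",
                        ifelse(indel_len %% 3L == 0L,
                               "nonframeshift", "frameshift"),
                        "exonic-unclassified"))
  }
  keep <- csq %in% retain
  out <- records[keep, , drop = FALSE]
  attr(out, "n_unclassified") <- sum(csq == "exonic-unclassified")
  attr(out, "n_no_contig") <- n_no_contig
  out
}

#' Filtering-funnel accounting
#'
#' Runs the full cascade (hard filters -> MAF -> consequence) on a
#' variant table and reports, per variant class, the record count at each
#' stage plus the percentage relative to the detection stage.
#'
#' @param records variant table (see [apply_hard_filters()]); needs
#'   `maf` and `consequence` (or a `gene_model`).
#' @param maf_threshold,maf_boundary passed to [maf_filter()].
#' @param gene_model,retain passed to [consequence_filter()].
#' @param classes variant classes to report (default: those present in
#'   the input, or both for an empty table).
#' @return object of class `variant_funnel`: data.frame with columns
#'   `variant_class`, `stage` (detected / quality / rare /
#'   protein_altering), `n`, `pct_of_detected`.
#' @export
variant_funnel <- function(records, maf_threshold = 0.01,
                           maf_boundary = "retain",
                           gene_model = NULL,
                           retain = protein_altering_classes(),
                           classes = NULL) {
  records$variant_class <- tolower(records$variant_class)
  s1 <- records
  s2f <- apply_hard_filters(records)
  s2 <- s2f[s2f$filter_pass, , drop = FALSE]
  s3 <- maf_filter(s2, threshold = maf_threshold, boundary = maf_boundary)
  s4 <- consequence_filter(s3, gene_model = gene_model, retain = retain)
  stages <- list(detected = s1, quality = s2, rare = s3,
                 protein_altering = s4)
  if (is.null(classes))
    classes <- if (nrow(records)) sort(unique(tolower(records$variant_class)))
      else c("indel", "snp")  # empty input: all-zero funnel for both classes
  out <- do.call(rbind, lapply(classes, function(cl) {
    n <- vapply(stages, function(s) sum(s$variant_class == cl), integer(1))
    if (any(diff(n) > 0L))
      stopf("internal error: funnel counts increased for class %s", cl)
    data.frame(variant_class = cl, stage = names(stages), n = unname(n),
               pct_of_detected = unname(100 * n / max(n[1L], 1L)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("variant_funnel", "data.frame"))
}

#' @export
print.variant_funnel <- function(x, ...) {
  cat("variant filtering funnel (counts; % of detected)\n")
  for (cl in unique(x$variant_class)) {
    xx <- x[x$variant_class == cl, ]
    cat(sprintf("  %-6s %s\n", cl,
                paste(sprintf("%s=%d (%.1f%%)", xx$stage, xx$n,
                              xx$pct_of_detected), collapse = " -> ")))
  }
  invisible(x)
}

#' Gene-level bi-allelic inactivation call
#'
#' Both functional copies of a gene are considered lost when the gene
#' carries a homozygous mutation, a heterozygous mutation on a single
#' remaining copy, or a homozygous deletion.  A homozygous mutation
#' reported together with a homozygous loss is contradictory and is
#' resolved to homozygous loss with a warning.
#'
#' @param gene gene symbol.
#' @param mutation `"none"`, `"het"` or `"hom"`.
#' @param copy_context `"normal"`, `"single-copy"`, `"homozygous loss"`
#'   or `"amplification"` (from the copy-number module or user input).
#' @return list of class `gene_event`: `gene`, `mutation`,
#'   `copy_context`, `biallelic` flag.
#' @export
biallelic_call <- function(gene, mutation = c("none", "het", "hom"),
                           copy_context = c("normal", "single-copy",
                                            "homozygous loss",
                                            "amplification")) {
  mutation <- match.arg(mutation)
  copy_context <- match.arg(copy_context)
  if (mutation == "hom" && copy_context == "homozygous loss") {
    warning(sprintf(
      "gene %s: homozygous mutation with homozygous loss is contradictory; resolved to homozygous loss",
      gene), call. = FALSE)
    mutation <- "none"
  }
  flag <- (mutation == "hom") ||
    (mutation == "het" && copy_context == "single-copy") ||
    (copy_context == "homozygous loss")
  structure(list(gene = gene, mutation = mutation,
                 copy_context = copy_context, biallelic = flag),
            class = "gene_event")
}

#' @export
print.gene_event <- function(x, ...) {
  cat(sprintf("%s: mutation %s, copy context %s -> %sbi-allelic inactivation\n",
              x$gene, x$mutation, x$copy_context,
              if (x$biallelic) "" else "no "))
  invisible(x)
}
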