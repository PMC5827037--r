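## Synthetic single-dose viability screen with known ground truth.
##
## The simulated assay mirrors the screening design used for the GEPNET
## cell-line panel: one 96-well treatment-plate series per cell line with
## 8 DMSO vehicle-control wells per plate, one full 96-well DMSO plate and
## one cell-free plate per cell-line experiment, single-dose treatment of
## the whole library.  Intensities follow
##   intensity = background + plate_effect * cellline_signal * (1 - effect)
##               * lognormal(noise)
## where the lognormal multiplier has mean 1 and the requested CV.

#' Describe a synthetic screen
#'
#' @param n_compounds number of library compounds.
#' @param class_map named character vector mapping compound id to a
#'   protein-target class.  Defaults to classes `"class_01"`, ... assigned
#'   in blocks of ten compounds.
#' @param cell_lines data.frame with columns `cell_line` and `group`.
#'   Defaults to the seven-line panel used in the original screen: two
#'   SINET lines, two PanNET lines and three non-tumourigenic lines.
#' @param wells_per_plate wells per plate (96).
#' @param dmso_controls_per_plate vehicle-control wells per treatment
#'   plate (8).
#' @param include_full_control_plate add a 96-well DMSO-only plate per
#'   cell line.
#' @param include_cellfree_plate add one cell-free background plate per
#'   cell line.
#' @param seed integer seed; the same design and seed reproduce
#'   byte-identical tables.
#' @return an object of class `screen_design`.
#' @export
screen_design <- function(n_compounds = 1224L,
                          class_map = NULL,
                          cell_lines = default_cell_lines(),
                          wells_per_plate = 96L,
                          dmso_controls_per_plate = 8L,
                          include_full_control_plate = TRUE,
                          include_cellfree_plate = TRUE,
                          seed = 1L) {
  assert_that(is_count(n_compounds), "n_compounds must be a positive integer")
  assert_that(is.data.frame(cell_lines) &&
                all(c("cell_line", "group") %in% names(cell_lines)),
              "cell_lines must have columns cell_line and group")
  assert_that(!anyDuplicated(cell_lines$cell_line),
              "duplicated cell line ids")
  assert_that(is_count(wells_per_plate) && is_count(dmso_controls_per_plate) &&
                dmso_controls_per_plate < wells_per_plate,
              "need dmso_controls_per_plate < wells_per_plate")
  ids <- sprintf("cmpd_%04d", seq_len(n_compounds))
  if (is.null(class_map)) {
    class_map <- setNames(sprintf("class_%02d",
                                  ((seq_len(n_compounds) - 1L) %/% 10L) + 1L),
                          ids)
  }
  assert_that(length(class_map) == n_compounds && !is.null(names(class_map)),
              "class_map must be named and cover all %d compounds", n_compounds)
  structure(list(n_compounds = as.integer(n_compounds),
                 compound_ids = names(class_map),
                 class_map = class_map,
                 cell_lines = cell_lines,
                 wells_per_plate = as.integer(wells_per_plate),
                 dmso_controls_per_plate = as.integer(dmso_controls_per_plate),
                 include_full_control_plate = isTRUE(include_full_control_plate),
                 include_cellfree_plate = isTRUE(include_cellfree_plate),
                 seed = as.integer(seed)),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("screen_design: %d compounds, %d cell lines (%s)\n",
              x$n_compounds, nrow(x$cell_lines),
              paste(sprintf("%s=%d", names(table(x$cell_lines$group)),
                            as.integer(table(x$cell_lines$group))),
                    collapse = ", ")))
  cat(sprintf("  %d-well plates, %d DMSO controls/plate, DMSO plate: %s, cell-free plate: %s\n",
              x$wells_per_plate, x$dmso_controls_per_plate,
              x$include_full_control_plate, x$include_cellfree_plate))
  invisible(x)
}

#' Default seven-line screening panel (2 SINET + 2 PanNET + 3 non-tumour)
#' @return data.frame with columns `cell_line`, `group`.
#' @export
default_cell_lines <- function() {
  data.frame(
    cell_line = c("SI1", "SI2", "PAN1", "PAN2", "NT1", "NT2", "NT3"),
    group = c("SINET", "SINET", "PanNET", "PanNET",
              "nontumour", "nontumour", "nontumour"),
    stringsAsFactors = FALSE)
}

#' Describe an injected group-selective viability effect
#'
#' @param target a target-class label (all compounds of that class) or a
#'   single compound id.
#' @param group cell-line group the effect applies to.
#' @param effect fractional viability reduction in `[0, 1]`; 0 is a null
#'   effect.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(target, group, effect) {
  assert_that(is.character(target) && length(target) == 1L,
              "target must be one class label or compound id")
  assert_that(is.character(group) && length(group) == 1L,
              "group must be one group label")
  assert_that(is_prob(effect) && length(effect) == 1L,
              "effect must be in [0, 1]")
  structure(list(target = target, group = group, effect = effect),
            class = "effect_spec")
}

#' Simulate a single-dose viability screen
#'
#' Generates raw well fluorescence intensities for every (compound, cell
#' line) pair plus the plate controls, and a ground-truth table of every
#' injected effect.
#'
#' @param design a [screen_design()].
#' @param effects list of [effect_spec()] objects (possibly empty: a null
#'   screen).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal well noise.
#' @param background_level mean background fluorescence (cell-free signal).
#' @param background_sd Gaussian SD of the additive background.
#' @param plate_effect_sd log-scale SD of the multiplicative plate effect.
#' @param cellline_signal mean viable-cell signal; scalar or named vector
#'   per cell line.
#' @return list of class `screen_sim` with elements `wells` (long table:
#'   plate, well, cell_line, role, compound_id, intensity), `annotation`
#'   (compound_id, class), `truth` (per-compound injected effects) and
#'   `design`.
#' @examples
#' sim <- generate_screen(screen_design(n_compounds = 40, seed = 7),
#'                        list(effect_spec("class_01", "PanNET", 0.5)))
#' head(sim$wells)
#' @export
generate_screen <- function(design, effects = list(),
                            noise_cv = 0.1,
                            background_level = 100,
                            background_sd = 0,
                            plate_effect_sd = 0.05,
                            cellline_signal = 10000) {
  assert_that(inherits(design, "screen_design"), "design must be a screen_design")
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  groups <- unique(design$cell_lines$group)
  classes <- unique(unname(design$class_map))
  ids <- design$compound_ids

  ## effect matrix: compounds x groups, combined multiplicatively
  surv <- matrix(1, nrow = length(ids), ncol = length(groups),
                 dimnames = list(ids, groups))
  truth <- list()
  for (ef in effects) {
    assert_that(inherits(ef, "effect_spec"), "effects must be effect_spec objects")
    assert_that(ef$group %in% groups, "unknown group '%s' in effect spec", ef$group)
    hit <- if (ef$target %in% classes) {
      ids[design$class_map == ef$target]
    } else if (ef$target %in% ids) {
      ef$target
    } else {
      stopf("effect targets unknown class or compound '%s'", ef$target)
    }
    surv[hit, ef$group] <- surv[hit, ef$group] * (1 - ef$effect)
    truth[[length(truth) + 1L]] <-
      data.frame(target = ef$target,
                 type = if (ef$target %in% classes) "class" else "compound",
                 group = ef$group, effect = ef$effect,
                 n_compounds = length(hit), stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(target = character(), type = character(), group = character(),
               effect = numeric(), n_compounds = integer())

  sig <- cellline_signal
  if (length(sig) == 1L && is.null(names(sig)))
    sig <- setNames(rep(sig, nrow(design$cell_lines)), design$cell_lines$cell_line)
  assert_that(all(design$cell_lines$cell_line %in% names(sig)),
              "cellline_signal must name every cell line")

  per_plate <- design$wells_per_plate - design$dmso_controls_per_plate
  n_plates <- ceiling(design$n_compounds / per_plate)
  labels <- well_labels()

  wells <- with_seed(design$seed, {
    out <- vector("list", nrow(design$cell_lines))
    for (li in seq_len(nrow(design$cell_lines))) {
      line <- design$cell_lines$cell_line[li]
      grp <- design$cell_lines$group[li]
      rows <- list()
      for (p in seq_len(n_plates)) {
        idx <- seq.int((p - 1L) * per_plate + 1L,
                       min(p * per_plate, design$n_compounds))
        plate_id <- sprintf("%s_P%02d", line, p)
        ## compounds fill the plate in library order; the last
        ## dmso_controls_per_plate wells carry vehicle controls
        cwell <- labels[seq_along(idx)]
        dwell <- labels[seq.int(design$wells_per_plate -
                                  design$dmso_controls_per_plate + 1L,
                                design$wells_per_plate)]
        rows[[length(rows) + 1L]] <- data.frame(
          plate = plate_id,
          well = c(cwell, dwell),
          cell_line = line,
          role = c(rep("compound", length(idx)),
                   rep("dmso", design$dmso_controls_per_plate)),
          compound_id = c(ids[idx], rep(NA_character_,
                                        design$dmso_controls_per_plate)),
          survival = c(surv[idx, grp], rep(1, design$dmso_controls_per_plate)),
          stringsAsFactors = FALSE)
      }
      if (design$include_full_control_plate) {
        rows[[length(rows) + 1L]] <- data.frame(
          plate = sprintf("%s_DMSO", line), well = labels,
          cell_line = line, role = "dmso", compound_id = NA_character_,
          survival = 1, stringsAsFactors = FALSE)
      }
      if (design$include_cellfree_plate) {
        rows[[length(rows) + 1L]] <- data.frame(
          plate = sprintf("%s_CELLFREE", line), well = labels,
          cell_line = line, role = "cellfree", compound_id = NA_character_,
          survival = 0, stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows)
      df$signal <- sig[[line]]
      out[[li]] <- df
    }
    w <- do.call(rbind, out)
    rownames(w) <- NULL
    plates <- unique(w$plate)
    pe <- setNames(exp(rnorm(length(plates), 0, plate_effect_sd)), plates)
    ## cell-free plates carry no cells, hence no plate (culture) effect
    pe[grepl("_CELLFREE$", names(pe))] <- 1
    bg <- rnorm(nrow(w), background_level, background_sd)
    noise <- rlnorm_cv(nrow(w), noise_cv)
    w$intensity <- bg + pe[w$plate] * w$signal * w$survival * noise
    w$survival <- NULL
    w$signal <- NULL
    w
  })

  structure(list(wells = wells,
                 annotation = data.frame(compound_id = ids,
                                         class = unname(design$class_map),
                                         stringsAsFactors = FALSE),
                 truth = truth,
                 design = design),
            class = "screen_sim")
}

#' Simulate a dose-response series around a four-parameter logistic curve
#'
#' Responses are drawn as `f4pl(dose) * lognormal(noise_cv)` for each
#' replicate, i.e. exactly on the curve when `noise_cv = 0`.
#'
#' @param true_params numeric vector `c(bottom, top, logIC50, hillslope)`
#'   (logIC50 in log10 molar; see [f4pl()]).
#' @param doses strictly positive doses (molar).
#' @param replicates replicates per dose (>= 1).
#' @param noise_cv CV of the multiplicative noise.
#' @param seed integer seed.
#' @param group optional group label attached to every row.
#' @return data.frame with columns `dose`, `replicate`, `response` (and
#'   `group` if given), plus attribute `true_params`.
#' @export
generate_dose_response <- function(true_params, doses, replicates = 3L,
                                   noise_cv = 0.05, seed = 1L, group = NULL) {
  assert_that(is.numeric(true_params) && length(true_params) == 4L,
              "true_params must be c(bottom, top, logIC50, hillslope)")
  assert_that(is.numeric(doses) && length(doses) >= 1L && all(doses > 0),
              "doses must be strictly positive (log-dose undefined otherwise)")
  assert_that(is_count(replicates), "replicates must be >= 1")
  df <- with_seed(seed, {
    d <- rep(doses, each = replicates)
    mu <- f4pl(d, true_params[1], true_params[2], true_params[3], true_params[4])
    data.frame(dose = d,
               replicate = rep(seq_len(replicates), times = length(doses)),
               response = mu * rlnorm_cv(length(d), noise_cv))
  })
  if (!is.null(group)) df$group <- group
  attr(df, "true_params") <- setNames(as.numeric(true_params),
                                      c("bottom", "top", "logIC50", "hillslope"))
  df
}
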