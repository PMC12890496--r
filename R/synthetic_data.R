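## Synthetic two-cohort, three-group study generator.
##
## Emulates the design used throughout the package: a discovery cohort with a
## wide spectral-cytometry-like panel (blood for every donor, thymus for a
## paired subcohort, ordinal hyperplasia grades) and a smaller validation
## cohort measured on a reduced CITE-seq-like panel sharing a common marker
## subset, with three donor groups (EOMG / LOMG / CTRL) and planted
## differentially abundant subpopulations of known direction and effect size.

#' Default marker panels for the two synthetic cohorts
#'
#' The discovery panel contains 18 markers; the validation panel is the
#' 11-marker subset that a small surface-protein (CITE-seq-like) panel would
#' cover. Their intersection is the common space used for cross-cohort label
#' transfer.
#'
#' @return named list with elements `train` and `val`.
#' @export
default_marker_panels <- function() {
  val <- c("CD3", "CD4", "CD8", "CD19", "CD56", "CD16", "TCRgd",
           "CD161", "CCR7", "CD45RA", "CD57")
  train <- c(val, "CD7", "CD2", "NKG2C", "NKp30", "CD127", "CD26", "CD25")
  list(train = train, val = val)
}

# Baseline lineage centroids on the transformed (arcsinh-like) scale:
# "positive" markers sit near 3, "negative" markers near 0.3.
.lineage_centroids <- function(markers) {
  lo <- 0.3
  cen <- matrix(lo, nrow = length(.LINEAGES), ncol = length(markers),
                dimnames = list(.LINEAGES, markers))
  set_if <- function(lineage, marker, value) {
    if (marker %in% markers) cen[lineage, marker] <<- value
  }
  set_if("B", "CD19", 3.0)
  set_if("CD4T", "CD3", 3.0); set_if("CD4T", "CD4", 3.0)
  set_if("CD4T", "CD26", 2.0); set_if("CD4T", "CD45RA", 1.5)
  set_if("CD8T", "CD3", 3.0); set_if("CD8T", "CD8", 3.0)
  set_if("CD8T", "CD7", 2.5); set_if("CD8T", "CD45RA", 1.5)
  set_if("CD8T", "CCR7", 0.8)
  set_if("gdT", "CD3", 3.0); set_if("gdT", "TCRgd", 3.0)
  set_if("gdT", "CD8", 0.8)
  set_if("NK", "CD56", 3.0); set_if("NK", "CD16", 2.0)
  set_if("NK", "CD7", 2.5); set_if("NK", "CD2", 1.5)
  set_if("NK", "CD57", 1.0); set_if("NK", "NKp30", 2.0)
  set_if("ILC", "CD127", 3.0); set_if("ILC", "CD161", 1.8)
  cen
}

#' Planted subpopulation template
#'
#' Describes one planted differentially abundant subpopulation: a tight
#' Gaussian blob inside a parent lineage whose donor-level frequency is
#' logit-normal around `baseline_freq` multiplied by a per-group effect
#' factor. Effect factors below 1 make the subpopulation smaller in that
#' group (e.g. `effect = c(LOMG = 0.5)` plants an "LOMG-low" population).
#'
#' @param name template name (used as the `true_subpop` truth label).
#' @param lineage parent lineage, one of `B`, `CD4T`, `CD8T`, `gdT`, `NK`,
#'   `ILC`.
#' @param markers named numeric vector of centroid overrides on the
#'   transformed scale; markers not named keep the parent lineage baseline.
#' @param baseline_freq baseline fraction of the parent lineage in (0, 1).
#' @param effect named multiplicative factors on `baseline_freq` per group;
#'   missing groups default to 1.
#' @param within_sd within-subpopulation marker standard deviation (> 0).
#' @param clone_param optional geometric clone-size parameter overriding the
#'   study-wide one for cells of this template (probability in (0, 1]; higher
#'   values mean smaller clones).
#' @param mait logical; marks the MAIT-like template whose cells receive the
#'   boosted invariant TCR-alpha rate.
#' @return object of class `subpop_template`.
#' @export
subpop_template <- function(name, lineage, markers, baseline_freq,
                            effect = c(EOMG = 1, LOMG = 1, CTRL = 1),
                            within_sd = 0.3, clone_param = NULL,
                            mait = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!lineage %in% .LINEAGES) {
    stop("unknown lineage '", lineage, "'")
  }
  if (!is.numeric(markers) || is.null(names(markers))) {
    stop("'markers' must be a named numeric vector of centroid overrides")
  }
  .assert_scalar_prob(baseline_freq, "baseline_freq", open0 = TRUE,
                      open1 = TRUE)
  full_effect <- c(EOMG = 1, LOMG = 1, CTRL = 1)
  if (!all(names(effect) %in% names(full_effect))) {
    stop("effect names must be among EOMG/LOMG/CTRL")
  }
  full_effect[names(effect)] <- effect
  if (any(full_effect < 0)) stop("effect factors must be non-negative")
  if (baseline_freq * max(full_effect) > 1) {
    stop("baseline_freq x max(effect) must not exceed 1")
  }
  if (!is.numeric(within_sd) || within_sd <= 0) stop("within_sd must be > 0")
  if (!is.null(clone_param)) {
    .assert_scalar_prob(clone_param, "clone_param", open0 = TRUE)
  }
  structure(list(name = name, lineage = lineage, markers = markers,
                 baseline_freq = baseline_freq, effect = full_effect,
                 within_sd = within_sd, clone_param = clone_param,
                 mait = isTRUE(mait)),
            class = "subpop_template")
}

#' Default planted subpopulations
#'
#' Three templates mirroring the discriminant populations the pipeline is
#' designed to recover: a naive (CCR7+CD45RA+) CD8 T population and a
#' MAIT-like (CD161+CD45RA-lo) CD8 T population, both planted low in LOMG,
#' and a highly differentiated CD57+CD16-hi NK population planted low in
#' EOMG. Baseline parent-lineage fractions (9%, 3%, 6%) match the scale of
#' the reported discriminant clusters; the default effect factor is 0.5
#' (a halving) in the low group.
#'
#' @param effect_low effect factor applied to the low group of each template.
#' @return list of [subpop_template] objects.
#' @export
mg_subpop_templates <- function(effect_low = 0.5) {
  list(
    subpop_template(
      name = "CD8T_naive", lineage = "CD8T",
      markers = c(CCR7 = 3.0, CD45RA = 3.2, CD7 = 2.8),
      baseline_freq = 0.09, effect = c(LOMG = effect_low),
      clone_param = 0.97),
    subpop_template(
      name = "CD8T_mait", lineage = "CD8T",
      markers = c(CD161 = 3.2, CD45RA = 0.4, CD7 = 0.6, CD26 = 3.0,
                  CCR7 = 0.4),
      baseline_freq = 0.03, effect = c(LOMG = effect_low),
      clone_param = 0.95, mait = TRUE),
    subpop_template(
      name = "NK_cd57", lineage = "NK",
      markers = c(CD57 = 3.3, CD16 = 3.2, NKG2C = 3.0, CD2 = 2.8,
                  NKp30 = 2.5),
      baseline_freq = 0.06, effect = c(EOMG = effect_low))
  )
}

#' Specification of a synthetic two-cohort study
#'
#' Collects every tunable of the generator. Defaults reproduce the study
#' design emulated throughout the package: a discovery cohort of 12 EOMG /
#' 16 LOMG / 20 control donors at 20,000 cells per donor with paired thymus
#' samples for 9 EOMG and 1 LOMG donor, and a validation cohort of 8 EOMG /
#' 6 LOMG donors (no controls) at 4,500 cells per donor.
#'
#' @param n_train,n_val named donor counts per group for the discovery and
#'   validation cohorts.
#' @param cells_per_donor named vector `c(train = , val = )` of blood cells
#'   per donor.
#' @param lineage_mixture probability vector over the six main lineages.
#' @param subpop_templates list of [subpop_template] objects.
#' @param marker_panels named list `list(train = , val = )` of marker names
#'   with a non-empty intersection.
#' @param noise_sd per-marker Gaussian standard deviation of background cells
#'   on the transformed scale.
#' @param donor_logit_sd between-donor standard deviation of subpopulation
#'   frequencies on the logit scale.
#' @param tissue_logit_sd additional logit-scale deviation of a donor's
#'   thymus frequency around their blood frequency.
#' @param hyperplasia_link slope linking the designated subpopulation's
#'   standardized log10 blood frequency to the latent hyperplasia score;
#'   negative values make low frequencies correspond to high grades.
#' @param hyperplasia_template name of the template driving hyperplasia.
#' @param n_thymus named counts of discovery donors per group that also
#'   contribute a thymus sample (and a hyperplasia grade).
#' @param thymus_cells_per_donor thymus cells per paired donor; defaults to
#'   the discovery blood cell count.
#' @param mait_fraction probability that a cell of the MAIT-like template
#'   carries the invariant Va7.2/Ja33 TCR-alpha pair.
#' @param mait_background same probability for all other CD8 T cells.
#' @param clone_size_param geometric clone-size parameter for CD8 T cells
#'   without a template-specific override (probability in (0, 1]; clone size
#'   is 1 + a geometric draw, so 1 forces all clones to singletons).
#' @param seed integer seed; identical specs with identical seeds generate
#'   byte-identical tables.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_train = c(EOMG = 12, LOMG = 16, CTRL = 20),
                           n_val = c(EOMG = 8, LOMG = 6, CTRL = 0),
                           cells_per_donor = c(train = 20000, val = 4500),
                           lineage_mixture = c(B = 0.12, CD4T = 0.40,
                                               CD8T = 0.25, gdT = 0.04,
                                               NK = 0.15, ILC = 0.04),
                           subpop_templates = mg_subpop_templates(),
                           marker_panels = default_marker_panels(),
                           noise_sd = 0.55,
                           donor_logit_sd = 0.3,
                           tissue_logit_sd = 0.25,
                           hyperplasia_link = -1.2,
                           hyperplasia_template = "NK_cd57",
                           n_thymus = c(EOMG = 9, LOMG = 1),
                           thymus_cells_per_donor = NULL,
                           mait_fraction = 0.26,
                           mait_background = 0.004,
                           clone_size_param = 0.8,
                           seed = 1L) {
  for (nm in c("EOMG", "LOMG", "CTRL")) {
    if (is.na(n_train[nm]) || n_train[nm] < 1) {
      stop("n_train must contain at least one donor per group")
    }
  }
  if (any(n_val < 0) || any(n_val[c("EOMG", "LOMG")] < 1)) {
    stop("n_val must contain at least one EOMG and one LOMG donor")
  }
  if (any(cells_per_donor[c("train", "val")] <= 0)) {
    stop("cells_per_donor must be positive")
  }
  if (any(lineage_mixture < 0) ||
      abs(sum(lineage_mixture) - 1) > 1e-8) {
    stop("lineage_mixture must be a probability vector summing to 1")
  }
  if (!all(names(lineage_mixture) %in% .LINEAGES)) {
    stop("lineage_mixture names must be main lineages")
  }
  stopifnot(is.list(subpop_templates))
  for (tpl in subpop_templates) {
    if (!inherits(tpl, "subpop_template")) {
      stop("subpop_templates must be a list of subpop_template objects")
    }
    if (!tpl$lineage %in% names(lineage_mixture) ||
        lineage_mixture[tpl$lineage] <= 0) {
      stop("template '", tpl$name,
           "' refers to a lineage outside the mixture support")
    }
  }
  # joint feasibility: per lineage, worst-case template fractions must fit
  for (lin in unique(vapply(subpop_templates, `[[`, "", "lineage"))) {
    tot <- sum(vapply(subpop_templates, function(t) {
      if (t$lineage == lin) t$baseline_freq * max(t$effect) else 0
    }, 0))
    if (tot >= 1) {
      stop("templates of lineage ", lin,
           " jointly exceed the parent lineage (sum of worst-case ",
           "frequencies >= 1)")
    }
  }
  common <- intersect(marker_panels$train, marker_panels$val)
  if (length(common) == 0L) stop("marker panels share no markers")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (donor_logit_sd <= 0) stop("donor_logit_sd must be > 0")
  .assert_scalar_prob(mait_fraction, "mait_fraction")
  .assert_scalar_prob(mait_background, "mait_background")
  .assert_scalar_prob(clone_size_param, "clone_size_param", open0 = TRUE)
  if (is.null(thymus_cells_per_donor)) {
    thymus_cells_per_donor <- unname(cells_per_donor["train"])
  }
  tpl_names <- vapply(subpop_templates, `[[`, "", "name")
  if (anyDuplicated(tpl_names)) stop("template names must be unique")
  if (!hyperplasia_template %in% tpl_names) {
    stop("hyperplasia_template must name one of the templates")
  }
  structure(list(
    n_train = n_train, n_val = n_val, cells_per_donor = cells_per_donor,
    lineage_mixture = lineage_mixture, subpop_templates = subpop_templates,
    marker_panels = marker_panels, noise_sd = noise_sd,
    donor_logit_sd = donor_logit_sd, tissue_logit_sd = tissue_logit_sd,
    hyperplasia_link = hyperplasia_link,
    hyperplasia_template = hyperplasia_template,
    n_thymus = n_thymus, thymus_cells_per_donor = thymus_cells_per_donor,
    mait_fraction = mait_fraction, mait_background = mait_background,
    clone_size_param = clone_size_param, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic two-cohort study specification\n")
  cat("  discovery donors: ",
      paste(names(x$n_train), x$n_train, sep = "=", collapse = " "), "\n")
  cat("  validation donors:",
      paste(names(x$n_val), x$n_val, sep = "=", collapse = " "), "\n")
  cat("  cells/donor: train", x$cells_per_donor[["train"]],
      " val", x$cells_per_donor[["val"]], "\n")
  cat("  templates:", paste(vapply(x$subpop_templates, `[[`, "", "name"),
                            collapse = ", "), "\n")
  cat("  common markers:",
      length(intersect(x$marker_panels$train, x$marker_panels$val)), "\n")
  invisible(x)
}

# Donor metadata for both cohorts. Ages and sexes are cosmetic but follow the
# demographics of the disease subgroups (EOMG onset < 50 years, female
# predominance; LOMG onset > 50).
.make_donor_meta <- function(spec) {
  mk <- function(prefix, counts, cohort) {
    groups <- rep(names(counts), counts)
    n <- length(groups)
    if (n == 0L) return(NULL)
    age <- numeric(n)
    age[groups == "EOMG"] <- runif(sum(groups == "EOMG"), 22, 49)
    age[groups == "LOMG"] <- runif(sum(groups == "LOMG"), 51, 82)
    age[groups == "CTRL"] <- runif(sum(groups == "CTRL"), 25, 75)
    p_f <- ifelse(groups == "EOMG", 0.7, ifelse(groups == "LOMG", 0.4, 0.5))
    data.frame(
      donor_id = sprintf("%s%02d", prefix, seq_len(n)),
      cohort = cohort,
      group = groups,
      age = round(age, 1),
      sex = ifelse(runif(n) < p_f, "F", "M"),
      thymectomy = groups == "EOMG",
      has_thymus = FALSE,
      hyperplasia_grade = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  meta <- rbind(mk("T", spec$n_train, "discovery"),
                mk("V", spec$n_val, "validation"))
  # paired thymus subcohort: first donors of each group in the discovery set
  for (g in names(spec$n_thymus)) {
    idx <- which(meta$cohort == "discovery" & meta$group == g)
    take <- head(idx, spec$n_thymus[[g]])
    meta$has_thymus[take] <- TRUE
  }
  rownames(meta) <- NULL
  meta
}

# Draw one donor's cells for one tissue. `logits` is the donor's logit-scale
# frequency per template (already tissue-adjusted).
.draw_donor_cells <- function(spec, donor_id, cohort, tissue, n_cells,
                              logits, panel, centroids) {
  mix <- spec$lineage_mixture
  lin_counts <- as.vector(rmultinom(1, n_cells, mix))
  names(lin_counts) <- names(mix)
  tpl_lineage <- vapply(spec$subpop_templates, `[[`, "", "lineage")
  tpl_names <- vapply(spec$subpop_templates, `[[`, "", "name")
  blocks_x <- list(); blocks_lin <- list(); blocks_sub <- list()
  for (lin in names(mix)) {
    n_lin <- lin_counts[[lin]]
    if (n_lin == 0L) next
    t_idx <- which(tpl_lineage == lin)
    probs <- if (length(t_idx)) plogis(logits[tpl_names[t_idx]]) else numeric(0)
    tot <- sum(probs)
    if (tot >= 1) probs <- probs * (0.95 / tot)  # guard, essentially unreached
    memb <- as.vector(rmultinom(1, n_lin, c(probs, 1 - sum(probs))))
    d <- length(panel)
    parts_x <- vector("list", length(t_idx) + 1L)
    parts_sub <- vector("list", length(t_idx) + 1L)
    for (j in seq_along(t_idx)) {
      n_j <- memb[j]
      if (n_j == 0L) { parts_x[[j]] <- NULL; next }
      tpl <- spec$subpop_templates[[t_idx[j]]]
      cen <- centroids[lin, panel]
      ov <- intersect(names(tpl$markers), panel)
      cen[ov] <- tpl$markers[ov]
      parts_x[[j]] <- matrix(rnorm(n_j * d, 0, tpl$within_sd), n_j, d) +
        matrix(cen, n_j, d, byrow = TRUE)
      parts_sub[[j]] <- rep(tpl$name, n_j)
    }
    n_bg <- memb[length(memb)]
    if (n_bg > 0L) {
      parts_x[[length(t_idx) + 1L]] <-
        matrix(rnorm(n_bg * d, 0, spec$noise_sd), n_bg, d) +
        matrix(centroids[lin, panel], n_bg, d, byrow = TRUE)
      parts_sub[[length(t_idx) + 1L]] <- rep("background", n_bg)
    }
    keep <- !vapply(parts_x, is.null, TRUE)
    x <- do.call(rbind, parts_x[keep])
    blocks_x[[lin]] <- x
    blocks_lin[[lin]] <- rep(lin, nrow(x))
    blocks_sub[[lin]] <- unlist(parts_sub[keep], use.names = FALSE)
  }
  x <- do.call(rbind, blocks_x)
  colnames(x) <- panel
  n <- nrow(x)
  cells <- data.frame(
    cell_id = sprintf("%s_%s_c%06d", donor_id, substr(tissue, 1, 2),
                      seq_len(n)),
    donor_id = donor_id, cohort = cohort, tissue = tissue,
    lineage = unlist(blocks_lin, use.names = FALSE),
    cluster = NA_character_,
    true_subpop = unlist(blocks_sub, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  cbind(cells, as.data.frame(x))
}

#' Generate a synthetic two-cohort study
#'
#' Draws both cohorts hierarchically: per donor, lineage counts are
#' multinomial in the lineage mixture; within a lineage, membership of each
#' planted subpopulation follows a donor-level logit-normal frequency around
#' `baseline_freq` times the donor group's effect factor; marker vectors are
#' Gaussian around the subpopulation (or lineage background) centroid.
#' Discovery donors flagged in `n_thymus` additionally receive a thymus cell
#' block (frequencies correlated with their blood frequencies on the logit
#' scale) and an ordinal hyperplasia grade (0-3) generated so that the grade
#' tracks the designated subpopulation's log blood frequency with slope sign
#' given by `hyperplasia_link`.
#'
#' The `lineage` column carries the generative truth; the gating module can
#' re-derive it from the marker intensities. All intensities are on the
#' transformed scale. The same spec and seed reproduce identical tables.
#'
#' @param spec a [synthetic_spec].
#' @return list with elements `train` (discovery cell table, blood + thymus),
#'   `val` (validation cell table) and `meta` (donor metadata).
#' @export
generate_study <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  set.seed(spec$seed)
  panels <- spec$marker_panels
  union_panel <- union(panels$train, panels$val)
  centroids <- .lineage_centroids(union_panel)
  meta <- .make_donor_meta(spec)
  tpl_names <- vapply(spec$subpop_templates, `[[`, "", "name")

  # donor-level blood logits per template
  base_logit <- function(tpl, group) {
    f <- tpl$baseline_freq * tpl$effect[[group]]
    qlogis(min(max(f, 1e-6), 1 - 1e-6))
  }
  logits <- matrix(NA_real_, nrow(meta), length(tpl_names),
                   dimnames = list(meta$donor_id, tpl_names))
  for (i in seq_len(nrow(meta))) {
    g <- if (meta$group[i] %in% c("EOMG", "LOMG", "CTRL")) meta$group[i]
         else "CTRL"
    for (j in seq_along(spec$subpop_templates)) {
      logits[i, j] <- rnorm(1, base_logit(spec$subpop_templates[[j]], g),
                            spec$donor_logit_sd)
    }
  }

  gen_cohort <- function(cohort, panel, n_cells) {
    ids <- meta$donor_id[meta$cohort == cohort]
    parts <- lapply(ids, function(d) {
      .draw_donor_cells(spec, d, cohort, "blood", n_cells,
                        logits[d, ], panel, centroids)
    })
    do.call(rbind, parts)
  }
  train <- gen_cohort("discovery", panels$train,
                      spec$cells_per_donor[["train"]])
  val <- gen_cohort("validation", panels$val, spec$cells_per_donor[["val"]])

  # paired thymus blocks
  thy_ids <- meta$donor_id[meta$has_thymus]
  if (length(thy_ids) > 0L) {
    thy <- lapply(thy_ids, function(d) {
      tl <- logits[d, ] + rnorm(ncol(logits), 0, spec$tissue_logit_sd)
      names(tl) <- colnames(logits)
      .draw_donor_cells(spec, d, "discovery", "thymus",
                        spec$thymus_cells_per_donor, tl, panels$train,
                        centroids)
    })
    train <- rbind(train, do.call(rbind, thy))
    # hyperplasia grades from the designated template's latent blood frequency
    lf <- log10(plogis(logits[thy_ids, spec$hyperplasia_template]))
    z <- if (length(lf) > 1 && sd(lf) > 0) (lf - mean(lf)) / sd(lf)
         else rep(0, length(lf))
    latent <- spec$hyperplasia_link * z + rnorm(length(z), 0, 0.6)
    meta$hyperplasia_grade[match(thy_ids, meta$donor_id)] <-
      findInterval(latent, c(-1, 0, 1))
  }
  rownames(train) <- rownames(val) <- NULL
  attr(train, "transformed") <- TRUE
  attr(val, "transformed") <- TRUE
  list(train = train, val = val, meta = meta)
}

#' Generate a synthetic TCR repertoire for CD8 T cells
#'
#' Every CD8 T cell receives a clone identifier (clone sizes are
#' 1 + geometric; clones are drawn within donor and subpopulation), a TCR
#' V-beta family (shared within a clone; the MAIT-like template's clones are
#' enriched for Vb6 and depleted of Vb7) and a TCR-alpha annotation: with
#' probability `mait_fraction` inside the MAIT-like template (and
#' `mait_background` elsewhere) the cell carries the invariant Va7.2/Ja33
#' pair; all other cells are guaranteed not to carry that exact pair.
#'
#' @param spec the [synthetic_spec] the cells were generated from.
#' @param cells a cell table containing CD8T-lineage rows.
#' @param seed optional integer seed.
#' @return repertoire table: `cell_id`, `donor_id`, `clone_id`, `v_alpha`,
#'   `j_alpha`, `v_beta_family`.
#' @export
generate_repertoire <- function(spec, cells, seed = NULL) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  if (!is.null(seed)) set.seed(seed)
  cd8 <- cells[cells$lineage == "CD8T", c("cell_id", "donor_id",
                                          "true_subpop")]
  if (nrow(cd8) == 0L) stop("cells contains no CD8T-lineage rows")
  tpl <- spec$subpop_templates
  tpl_names <- vapply(tpl, `[[`, "", "name")
  mait_tpl <- tpl_names[vapply(tpl, `[[`, TRUE, "mait")]
  clone_param_of <- function(sub) {
    j <- match(sub, tpl_names)
    if (!is.na(j) && !is.null(tpl[[j]]$clone_param)) tpl[[j]]$clone_param
    else spec$clone_size_param
  }
  vb_fams <- paste0("Vb", 1:20)
  w <- exp(-0.12 * (0:19)); vb_base <- w / sum(w)
  vb_mait <- vb_base
  vb_mait[vb_fams == "Vb6"] <- 0
  vb_mait[vb_fams == "Vb7"] <- 0.1 * vb_base[vb_fams == "Vb7"]
  vb_mait <- vb_mait * (0.55 / sum(vb_mait))
  vb_mait[vb_fams == "Vb6"] <- 0.45
  va_pool <- c("Va1.2", "Va2", "Va7.2", "Va8.1", "Va12.1", "Va17", "Va19")
  va_p <- c(0.18, 0.18, 0.06, 0.16, 0.16, 0.14, 0.12)
  ja_pool <- paste0("Ja", c(9, 12, 20, 33, 42, 49))

  out <- vector("list", 0L)
  strata <- split(seq_len(nrow(cd8)),
                  paste(cd8$donor_id, cd8$true_subpop, sep = "\r"))
  for (key in names(strata)) {
    rows <- strata[[key]]
    n <- length(rows)
    sub <- cd8$true_subpop[rows[1]]
    donor <- cd8$donor_id[rows[1]]
    cp <- clone_param_of(sub)
    sizes <- if (cp >= 1) rep(1L, n) else {
      s <- rgeom(n, cp) + 1L
      cum <- cumsum(s)
      k <- which(cum >= n)[1]
      s <- s[seq_len(k)]
      s[k] <- s[k] - (cum[k] - n)
      s
    }
    clone_ids <- sprintf("%s_%s_cl%05d", donor, abbreviate(sub, 6),
                         seq_along(sizes))
    cell_clone <- rep(clone_ids, sizes)
    p_vb <- if (sub %in% mait_tpl) vb_mait else vb_base
    clone_vb <- sample(vb_fams, length(sizes), replace = TRUE, prob = p_vb)
    cell_vb <- rep(clone_vb, sizes)
    p_mait <- if (sub %in% mait_tpl) spec$mait_fraction
              else spec$mait_background
    is_mait <- runif(n) < p_mait
    va <- sample(va_pool, n, replace = TRUE, prob = va_p)
    ja <- sample(ja_pool, n, replace = TRUE)
    redraw <- !is_mait & va == "Va7.2" & ja == "Ja33"
    if (any(redraw)) {
      ja[redraw] <- sample(setdiff(ja_pool, "Ja33"), sum(redraw),
                           replace = TRUE)
    }
    va[is_mait] <- "Va7.2"
    ja[is_mait] <- "Ja33"
    out[[key]] <- data.frame(
      cell_id = cd8$cell_id[rows], donor_id = donor,
      clone_id = cell_clone, v_alpha = va, j_alpha = ja,
      v_beta_family = cell_vb, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a synthetic study specification from YAML
#'
#' Scalar fields map directly to [synthetic_spec] arguments; named vectors
#' (donor counts, lineage mixture, panels) are given as YAML mappings, and
#' `subpop_templates` as a list of mappings with the [subpop_template]
#' fields.
#'
#' @param path path to a YAML file.
#' @return a [synthetic_spec].
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$subpop_templates)) {
    y$subpop_templates <- lapply(y$subpop_templates, function(t) {
      t$markers <- unlist(t$markers)
      t$effect <- unlist(t$effect)
      do.call(subpop_template, t)
    })
  }
  for (nm in c("n_train", "n_val", "cells_per_donor", "lineage_mixture",
               "n_thymus")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  do.call(synthetic_spec, y)
}

#' Write / read a cell table as CSV
#'
#' Plain-text round trip for cell tables and donor metadata. The
#' `transformed` flag is preserved as an attribute column-free convention:
#' tables written by the generator are on the transformed scale.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_cell_table` returns the cell table with marker columns
#'   numeric.
#' @export
write_cell_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  attr(x, "transformed") <- TRUE
  x
}
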