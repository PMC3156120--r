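#' Describe a full trajectory-directionality analysis
#'
#' @param groups A data frame with columns `strain`, `treatment` and
#'   optionally `center_day`. Missing center days default to 0 for sham and
#'   1 for IRI (override to 0 for strains without an initial surgery
#'   response, e.g. immunodeficient mice).
#' @param pcs Number of principal components to analyze (default 3).
#' @param full_dim If `TRUE`, skip PCA and compute directions in the full
#'   retained-miR space.
#' @param knockout Optional miR ids to digitally knock out (normalized values
#'   set to 0) before PCA. Mutually exclusive with `subset`.
#' @param subset Optional miR ids to restrict the analysis to (PCA re-fitted
#'   on these only).
#' @param reps Monte-Carlo replicates per null distribution (default 10000).
#' @param seed Integer seed for all Monte-Carlo draws.
#' @param floor Detection floor for normalization (default 200).
#' @param mean_threshold Mean-intensity filter threshold (default 200).
#' @param filter_scope `"plan"` (mean over the samples entering this
#'   analysis; default) or `"all"` (mean over every sample in the sheet).
#' @param proximity Optional data frame with columns `test` and `reference`
#'   (group labels `"strain treatment"`): for each row the test group's
#'   spherical-SD center is compared to the reference group's, and a
#'   proximity P-value is computed by randomizing the test group only.
#' @return An `analysis_plan` list.
#' @export
analysis_plan <- function(groups, pcs = 3, full_dim = FALSE, knockout = NULL,
                          subset = NULL, reps = 10000, seed = 1L,
                          floor = 200, mean_threshold = 200,
                          filter_scope = c("plan", "all"),
                          proximity = NULL) {
  groups <- tibble::as_tibble(groups)
  if (!all(c("strain", "treatment") %in% names(groups)) || nrow(groups) == 0) {
    abort("'groups' needs at least one row with columns strain, treatment")
  }
  if (!all(groups$treatment %in% c("sham", "IRI"))) {
    abort("group treatments must be \"sham\" or \"IRI\"")
  }
  if (!"center_day" %in% names(groups)) groups$center_day <- NA_integer_
  groups$center_day <- ifelse(
    is.na(groups$center_day),
    ifelse(groups$treatment == "sham", 0L, 1L),
    as.integer(groups$center_day)
  )
  groups$label <- paste(groups$strain, groups$treatment)
  if (anyDuplicated(groups$label)) abort("duplicate groups in plan")
  if (!is.null(knockout) && !is.null(subset)) {
    abort("'knockout' and 'subset' are mutually exclusive")
  }
  structure(
    list(groups = groups, pcs = pcs, full_dim = isTRUE(full_dim),
         knockout = knockout, subset = subset, reps = as.integer(reps),
         seed = as.integer(seed), floor = floor,
         mean_threshold = mean_threshold,
         filter_scope = match.arg(filter_scope),
         proximity = if (!is.null(proximity)) tibble::as_tibble(proximity)),
    class = "analysis_plan"
  )
}

#' Run the full trajectory-directionality analysis
#'
#' Orchestrates preprocessing (mean filter, floor, log-ratio normalization,
#' optional digital knockout or subset restriction), PCA projection (or
#' full-dimension analysis), spherical summaries per group (enclosing-cap
#' radius, spherical SD) with random-walk directionality P-values, pairwise
#' separation/discrimination with Monte-Carlo P-values, and optional
#' proximity tests.
#'
#' @param x Expression tibble (`mir_id` + sample columns) of raw intensities.
#' @param sheet Sample sheet tibble.
#' @param plan An [analysis_plan()].
#' @return A `mir_report` list with elements `meta`, `groups`, `pairs`,
#'   `proximity`, `projections`, and (attribute-free) echo of the plan.
#' @export
run_analysis <- function(x, sheet, plan) {
  if (!inherits(plan, "analysis_plan")) abort("'plan' must be an analysis_plan")
  x <- validate_expression_matrix(x)
  sheet <- validate_sample_sheet(sheet)
  set.seed(plan$seed)

  g <- plan$groups
  arm_ok <- paste(sheet$strain, sheet$treatment)
  missing_groups <- setdiff(g$label, arm_ok)
  if (length(missing_groups) > 0) {
    abort(paste0("plan group(s) not present in the sample sheet: ",
                 toString(missing_groups)))
  }
  scope_samples <- if (plan$filter_scope == "all") {
    sheet$sample_id
  } else {
    sheet$sample_id[arm_ok %in% g$label |
                      (sheet$treatment == "naive" &
                         sheet$strain %in% g$strain)]
  }

  kept <- filter_by_mean(x, plan$mean_threshold, scope_samples)
  norm <- normalize_samples(kept, sheet, floor = plan$floor)
  if (!is.null(plan$knockout)) norm <- digital_knockout(norm, plan$knockout)
  if (!is.null(plan$subset)) {
    unknown <- setdiff(plan$subset, mir_cols(norm))
    if (length(unknown) > 0) {
      abort(paste0("unknown miR id(s) in subset: ", toString(unknown)))
    }
    norm <- dplyr::select(norm, dplyr::all_of(c(META_COLS, plan$subset)))
  }

  series <- purrr::pmap(g, function(strain, treatment, ...) {
    extract_series(norm, strain, treatment)
  })
  fit_rows <- dplyr::distinct(dplyr::bind_rows(series))

  if (plan$full_dim) {
    k <- length(mir_cols(norm))
    proj <- purrr::map(series, ~ .x)
    model <- NULL
  } else {
    model <- fit_pca(fit_rows)
    k <- min(plan$pcs, length(model$variance_fractions))
    proj <- purrr::map(series, ~ project_series(model, .x, k = k))
  }

  nulls <- list()
  get_null <- function(kind, key, make) {
    id <- paste(kind, key, sep = ":")
    if (is.null(nulls[[id]])) nulls[[id]] <<- make()
    nulls[[id]]
  }

  per_group <- purrr::pmap(
    list(proj, g$center_day, g$label),
    function(p, cday, label) {
      ds <- center_projected_directions(p, cday)
      circ <- min_enclosing_circle(ds)
      sp <- spherical_sd(ds)
      n_dir <- nrow(ds$directions)
      null <- get_null("radius", paste(n_dir, k), function() {
        null_radius_distribution(n_dir, d = k, n_reps = plan$reps)
      })
      list(ds = ds, circ = circ, sp = sp,
           row = tibble::tibble(
             group = label, n_directions = n_dir, center_day = cday,
             radius_deg = circ$radius_deg, sd_deg = sp$sd_deg,
             p_directionality = p_value_directionality(circ$radius_deg, null)
           ))
    })
  groups_tbl <- dplyr::bind_rows(purrr::map(per_group, "row"))

  pairs_tbl <- NULL
  if (nrow(g) >= 2) {
    idx <- utils::combn(nrow(g), 2)
    pairs_tbl <- purrr::map(seq_len(ncol(idx)), function(j) {
      a <- per_group[[idx[1, j]]]
      b <- per_group[[idx[2, j]]]
      sep <- angular_distance(a$sp$sd_center, b$sp$sd_center)
      mx <- max(a$sp$sd_deg, b$sp$sd_deg)
      disc <- if (mx < 1e-9) Inf else sep / mx
      na <- nrow(a$ds$directions)
      nb <- nrow(b$ds$directions)
      null <- get_null("disc", paste(min(na, nb), max(na, nb), k), function() {
        null_discrimination_distribution(na, nb, d = k, n_reps = plan$reps)
      })
      tibble::tibble(
        group_a = g$label[idx[1, j]], group_b = g$label[idx[2, j]],
        separation_deg = sep, discrimination = disc,
        p_discrimination = p_value_discrimination(disc, null)
      )
    }) %>% dplyr::bind_rows()
  }

  proximity_tbl <- NULL
  if (!is.null(plan$proximity)) {
    proximity_tbl <- purrr::pmap(plan$proximity, function(test, reference) {
      it <- match(test, g$label)
      ir <- match(reference, g$label)
      if (is.na(it) || is.na(ir)) {
        abort(paste0("proximity pair refers to unknown group: ",
                     test, " / ", reference))
      }
      a <- per_group[[it]]
      b <- per_group[[ir]]
      obs <- angular_distance(a$sp$sd_center, b$sp$sd_center)
      null <- null_proximity_distribution(
        nrow(a$ds$directions), d = k, reference_center = b$sp$sd_center,
        n_reps = plan$reps
      )
      tibble::tibble(test = test, reference = reference,
                     angle_deg = obs,
                     p_proximity = p_value_proximity(obs, null))
    }) %>% dplyr::bind_rows()
  }

  projections <- purrr::map2(proj, g$label, function(p, label) {
    if (plan$full_dim) {
      tibble::tibble(series = label, day = p$day)
    } else {
      dplyr::bind_cols(tibble::tibble(series = label),
                       dplyr::select(p, "day", dplyr::starts_with("pc")))
    }
  }) %>% dplyr::bind_rows()

  centers <- purrr::map2(per_group, g$label, function(pg, label) {
    tibble::tibble(group = label,
                   circle_center = list(as.numeric(pg$circ$center)),
                   sd_center = list(setNames(as.numeric(pg$sp$sd_center),
                                             colnames(pg$ds$directions))))
  }) %>% dplyr::bind_rows()

  structure(
    list(
      meta = list(
        seed = plan$seed, reps = plan$reps, ambient_dim = k,
        full_dim = plan$full_dim, n_mirs_retained = length(mir_cols(norm)),
        floor = plan$floor, mean_threshold = plan$mean_threshold,
        filter_scope = plan$filter_scope,
        knockout = plan$knockout, subset = plan$subset,
        n_directions = groups_tbl$n_directions,
        variance_fractions = if (!is.null(model)) {
          model$variance_fractions
        },
        cumulative_variance_k = if (!is.null(model)) {
          cumulative_variance(model, k)
        }
      ),
      groups = groups_tbl,
      pairs = pairs_tbl,
      proximity = proximity_tbl,
      projections = projections,
      centers = centers
    ),
    class = "mir_report"
  )
}

#' @export
print.mir_report <- function(x, ...) {
  cat("<mir_report> ", nrow(x$groups), " group(s), d = ", x$meta$ambient_dim,
      ", ", x$meta$n_mirs_retained, " miRs retained, seed ", x$meta$seed,
      "\n", sep = "")
  print(x$groups)
  if (!is.null(x$pairs) && nrow(x$pairs) > 0) print(x$pairs)
  if (!is.null(x$proximity) && nrow(x$proximity) > 0) print(x$proximity)
  invisible(x)
}

#' @export
tidy.mir_report <- function(x, ...) x$groups

#' @export
glance.mir_report <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    ambient_dim = x$meta$ambient_dim,
    n_mirs_retained = x$meta$n_mirs_retained,
    reps = x$meta$reps,
    seed = x$meta$seed,
    min_p_directionality = min(x$groups$p_directionality)
  )
}

#' Compare an analysis with and without a digital knockout
#'
#' Runs [run_analysis()] twice with the same seed — once as planned and once
#' with the miRs in `mirs` digitally knocked out — and tabulates the changes
#' in radii, spherical SDs, separations and discriminations.
#'
#' @inheritParams run_analysis
#' @param mirs miR ids to knock out.
#' @return A list `baseline` (mir_report), `knockout` (mir_report) and
#'   `deltas` (list of tibbles `groups`, `pairs` holding knockout minus
#'   baseline differences).
#' @export
run_knockout_comparison <- function(x, sheet, plan, mirs) {
  if (!is.null(plan$knockout) || !is.null(plan$subset)) {
    abort("the plan must not already carry a knockout or subset")
  }
  base <- run_analysis(x, sheet, plan)
  ko_plan <- plan
  ko_plan$knockout <- mirs
  ko <- run_analysis(x, sheet, ko_plan)
  d_groups <- dplyr::inner_join(base$groups, ko$groups, by = "group",
                                suffix = c("_base", "_ko")) %>%
    dplyr::transmute(
      .data$group,
      d_radius_deg = .data$radius_deg_ko - .data$radius_deg_base,
      d_sd_deg = .data$sd_deg_ko - .data$sd_deg_base,
      d_p_directionality = .data$p_directionality_ko -
        .data$p_directionality_base
    )
  d_pairs <- NULL
  if (!is.null(base$pairs)) {
    d_pairs <- dplyr::inner_join(base$pairs, ko$pairs,
                                 by = c("group_a", "group_b"),
                                 suffix = c("_base", "_ko")) %>%
      dplyr::transmute(
        .data$group_a, .data$group_b,
        d_separation_deg = .data$separation_deg_ko -
          .data$separation_deg_base,
        d_discrimination = .data$discrimination_ko -
          .data$discrimination_base
      )
  }
  list(baseline = base, knockout = ko,
       deltas = list(groups = d_groups, pairs = d_pairs))
}
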