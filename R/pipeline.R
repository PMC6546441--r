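# End-to-end orchestration: calibrate -> score -> analyze.

#' Build a pipeline configuration
#'
#' Collects paths, simulation parameters, colour-space constants and seeds
#' for [run_full_pipeline()].  With no image/cohort paths the pipeline runs
#' on synthetic data generated from the packaged study conditions.
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its own sub-stream from it.
#' @param nsim parametric-bootstrap simulations per retained term (0 skips
#'   the bootstrap; 999 in routine use).
#' @param n_wings_per_cell synthetic wings per Td x Ta x Sex cell.
#' @param wing_params a [wing_sim_params()]; default study conditions.
#' @param cohort_params a [cohort_sim_params()]; default study conditions.
#' @param standards_csv optional gray-standards CSV for calibration.
#' @param calibration_degree polynomial degree for calibration.
#' @param images_dir,annotations_dir optional directories of real wing
#'   images and matching `<name>.json` annotations (instead of simulation).
#' @param cohort_csv optional observed cohort table (instead of simulation).
#' @param reference_brown,reference_green HSB triples for the assay patches.
#' @param nAGQ integrator setting for the GLMM fits (see [fit_glmm()]).
#' @param force overwrite differing existing outputs instead of erroring.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, nsim = 0L,
                            n_wings_per_cell = 16L,
                            wing_params = NULL, cohort_params = NULL,
                            standards_csv = NULL, calibration_degree = 1L,
                            images_dir = NULL, annotations_dir = NULL,
                            cohort_csv = NULL,
                            reference_brown = c(25, 0.60, 0.50),
                            reference_green = c(130, 0.60, 0.50),
                            nAGQ = 1L, force = FALSE) {
  if (nsim < 0) stop_wc("nsim must be >= 0")
  for (hsb in list(reference_brown, reference_green)) {
    if (hsb[1] < 0 || hsb[1] >= 360 || any(hsb[2:3] < 0) || any(hsb[2:3] > 1)) {
      stop_wc("reference HSB values out of range")
    }
  }
  for (p in c(standards_csv, images_dir, annotations_dir, cohort_csv)) {
    if (!is.null(p) && !file.exists(p)) stop_wc("path does not exist: ", p)
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), nsim = as.integer(nsim),
    n_wings_per_cell = as.integer(n_wings_per_cell),
    wing_params = wing_params, cohort_params = cohort_params,
    standards_csv = standards_csv,
    calibration_degree = as.integer(calibration_degree),
    images_dir = images_dir, annotations_dir = annotations_dir,
    cohort_csv = cohort_csv,
    reference_brown = reference_brown, reference_green = reference_green,
    nAGQ = as.integer(nAGQ), force = isTRUE(force)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#' @param path config file (`.json`, `.yaml`/`.yml`).
#' @param ... overrides passed to [pipeline_config()] (flags beat file
#'   values).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_wc("the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else stop_wc("config must be .json or .yaml")
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

# write a file only if absent, identical, or force: no silent overwrite of
# differing outputs
.write_checked <- function(path, writer, force) {
  if (file.exists(path)) {
    tmp <- tempfile(fileext = paste0(".", tools::file_ext(path)))
    on.exit(unlink(tmp), add = TRUE)
    writer(tmp)
    if (unname(tools::md5sum(tmp)) != unname(tools::md5sum(path))) {
      if (!force) {
        stop_wc("output ", path, " exists and differs; use force = TRUE")
      }
      file.copy(tmp, path, overwrite = TRUE)
    }
  } else {
    writer(path)
  }
  invisible(path)
}

.write_csv_checked <- function(d, path, force) {
  .write_checked(path, function(p) {
    utils::write.csv(d, p, row.names = FALSE, quote = FALSE)
  }, force)
}

#' Score a set of wings
#'
#' @param wings list of elements each holding `image`, `annotation`
#'   (landmarks + boundaries), `Td`, `Ta`, `sex`, `individual`.
#' @param curve calibration curve applied before sampling.
#' @return list of data.frames `contrast` (tidy:
#'   `individual,sex,Td,Ta,element,contrast`) and `crypsis`
#'   (`individual,sex,Td,Ta,crypsis_brown,crypsis_green`).
#' @export
score_wing_set <- function(wings, curve = identity_calibration()) {
  ctr <- list(); cry <- list()
  for (i in seq_along(wings)) {
    w <- wings[[i]]
    img <- apply_calibration(w$image, curve)
    sc <- score_wing(img, w$annotation$landmarks, w$annotation$boundaries)
    meta <- data.frame(individual = w$individual, sex = w$sex,
                       Td = w$Td, Ta = w$Ta %||% NA)
    ctr[[i]] <- cbind(meta[rep(1, nrow(sc$contrast)), , drop = FALSE],
                      element = sc$contrast$element,
                      contrast = sc$contrast$distance)
    cry[[i]] <- cbind(meta, crypsis_brown = sc$crypsis_brown,
                      crypsis_green = sc$crypsis_green)
  }
  list(contrast = do.call(rbind, ctr), crypsis = do.call(rbind, cry))
}

.simulate_wing_set <- function(config) {
  wp <- config$wing_params %||% wing_sim_params(seed = derive_seed(config$seed, "wings"))
  cells <- expand.grid(Td = c(19, 27), Ta = c(19, 27), sex = c("F", "M"),
                       stringsAsFactors = FALSE)
  wings <- list()
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (k in seq_len(config$n_wings_per_cell)) {
      idx <- idx + 1L
      w <- generate_wing_image(wp, cells$Td[ci], cells$sex[ci],
                               individual = idx)
      w$Ta <- cells$Ta[ci]
      wings[[idx]] <- w
    }
  }
  wings
}

.load_wing_set <- function(config) {
  imgs <- sort(list.files(config$images_dir, "\\.(png|tif|tiff)$",
                          full.names = TRUE))
  if (!length(imgs)) stop_wc("no images found in ", config$images_dir)
  lapply(imgs, function(f) {
    base <- tools::file_path_sans_ext(basename(f))
    ann_path <- file.path(config$annotations_dir, paste0(base, ".json"))
    if (!file.exists(ann_path)) stop_wc("missing annotation for ", base)
    meta <- strsplit(base, "_")[[1]] # <id>_<sex>_Td<Td>_Ta<Ta>
    list(image = read_wing_image(f), annotation = read_annotation_json(ann_path),
         individual = meta[1], sex = meta[2],
         Td = as.numeric(sub("Td", "", meta[3])),
         Ta = as.numeric(sub("Ta", "", meta[4])))
  })
}

.term_tests <- function(data, sel, fitter, nsim, seed, nAGQ = 1L) {
  rows <- list()
  for (tm in .removable_terms(sel$spec$fixed)) {
    sp_r <- sel$spec
    sp_r$fixed <- setdiff(sel$spec$fixed, tm)
    fit_r <- if (identical(fitter, fit_glmm)) fitter(data, sp_r, nAGQ = nAGQ)
    else fitter(data, sp_r)
    tst <- lrt(sel$fit, fit_r)
    p_boot <- NA_real_
    if (nsim > 0) {
      tst <- parametric_bootstrap_p(sel$fit, fit_r, nsim = nsim,
                                    seed = derive_seed(seed, paste0("boot:", tm)))
      p_boot <- tst$p_bootstrap
    }
    rows[[tm]] <- data.frame(term = tm, chisq = tst$statistic, df = tst$df,
                             p_lrt = tst$p_lrt, p_boot = p_boot)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), chisq = numeric(0),
                      df = integer(0), p_lrt = numeric(0),
                      p_boot = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in order: scanner calibration (if standards are supplied),
#' wing scoring (synthetic or from image/annotation directories),
#' pigmentation linear models, and the behavioural GLMM analyses
#' (preference and activity: BIC backward selection, term LRTs with
#' optional parametric bootstrap, Tukey post hoc letters, and exact 1:1
#' preference tests per cell).  All outputs land in `config$out_dir`;
#' rerunning with the same config and seed reproduces them byte for byte,
#' and differing existing outputs are never overwritten silently.
#'
#' @param config a [pipeline_config()].
#' @return run report (list), invisibly; side effect: CSV/JSON outputs and
#'   `manifest.json` in `out_dir`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(seed = config$seed)
  stage <- "calibration"
  tryCatch({
    curve <- if (!is.null(config$standards_csv)) {
      fit_calibration(read_standards_csv(config$standards_csv),
                      degree = config$calibration_degree)
    } else identity_calibration()
    .write_checked(out("curve.json"),
                   function(p) write_calibration_json(curve, p),
                   config$force)
    report$calibration <- curve

    stage <- "scoring"
    wings <- if (is.null(config$images_dir)) .simulate_wing_set(config)
    else .load_wing_set(config)
    scores <- score_wing_set(wings, curve)
    .write_csv_checked(scores$contrast, out("scores_contrast.csv"), config$force)
    .write_csv_checked(scores$crypsis, out("scores_crypsis.csv"), config$force)
    report$n_wings <- length(wings)

    stage <- "pigmentation"
    pig <- list()
    for (el in unique(scores$contrast$element)) {
      d <- scores$contrast[scores$contrast$element == el, ]
      d$score <- d$contrast
      d$Td <- factor(d$Td, levels = c(27, 19)); d$Ta <- factor(d$Ta, levels = c(27, 19))
      d$Sex <- factor(d$sex, levels = c("M", "F"))
      fit <- fit_lmm(d, mixed_model_spec("score", c("Td", "Ta", "Sex"),
                                         random = character(0),
                                         family = "gaussian"))
      ft <- f_tests(fit)
      ft$response <- paste0("contrast_", el)
      ft$td19_estimate <- unname(stats::coef(fit)["Td19"])
      pig[[el]] <- ft
    }
    dcry <- scores$crypsis
    dcry$score <- dcry$crypsis_brown
    dcry$Td <- factor(dcry$Td, levels = c(27, 19)); dcry$Ta <- factor(dcry$Ta, levels = c(27, 19))
    dcry$Sex <- factor(dcry$sex, levels = c("M", "F"))
    cry_fit <- fit_lmm(dcry, mixed_model_spec("score", c("Td", "Ta", "Sex"),
                                              random = character(0),
                                              family = "gaussian"))
    ft <- f_tests(cry_fit)
    ft$response <- "crypsis_brown"
    ft$td19_estimate <- unname(stats::coef(cry_fit)["Td19"])
    pig$crypsis <- ft
    pig_tab <- do.call(rbind, pig)
    rownames(pig_tab) <- NULL
    .write_csv_checked(pig_tab, out("pigmentation_tests.csv"), config$force)
    cry_ph <- posthoc_pairwise(cry_fit, c("Td", "Ta", "Sex"))
    .write_csv_checked(
      cry_ph$emmeans[, c("Td", "Ta", "Sex", "emmean", "SE", "letters")],
      out("posthoc_crypsis.csv"), config$force
    )
    report$pigmentation <- pig_tab

    stage <- "behaviour"
    obs <- if (is.null(config$cohort_csv)) {
      cp <- config$cohort_params %||%
        cohort_sim_params(seed = derive_seed(config$seed, "cohort-stage"))
      generate_cohort_series(cp)
    } else read_cohort_csv(config$cohort_csv)
    .write_csv_checked(obs, out("cohorts.csv"), config$force)

    full <- mixed_model_spec("preference")
    pref <- build_preference_response(obs)
    sel_pref <- backward_select_bic(pref, full, nAGQ = config$nAGQ)
    pref_tab <- .term_tests(pref, sel_pref, fit_glmm, config$nsim,
                            config$seed, config$nAGQ)
    .write_csv_checked(pref_tab, out("preference_terms.csv"), config$force)

    act <- build_activity_response(obs)
    sel_act <- backward_select_bic(act, mixed_model_spec("activity"),
                                   nAGQ = config$nAGQ)
    act_tab <- .term_tests(act, sel_act, fit_glmm, config$nsim,
                           config$seed, config$nAGQ)
    .write_csv_checked(act_tab, out("activity_terms.csv"), config$force)

    report$preference <- list(selected = sel_pref$spec$fixed,
                              trace = sel_pref$trace, tests = pref_tab,
                              fit = sel_pref$fit)
    report$activity <- list(selected = sel_act$spec$fixed,
                            trace = sel_act$trace, tests = act_tab,
                            fit = sel_act$fit)

    stage <- "posthoc"
    # letters over the cells of the factors retained in each selected model
    ph_factors <- function(sel) {
      f <- intersect(c("Td", "Ta", "Sex"),
                     unique(unlist(strsplit(sel$spec$fixed, ":"))))
      if (!length(f)) NULL else f
    }
    fpref <- ph_factors(sel_pref)
    if (!is.null(fpref)) {
      ph <- posthoc_pairwise(sel_pref$fit, fpref)
      .write_csv_checked(
        ph$emmeans[, c(fpref, "emmean", "SE", "letters")],
        out("posthoc_preference.csv"), config$force
      )
      report$preference$posthoc <- ph
    }
    fact <- ph_factors(sel_act)
    if (!is.null(fact)) {
      ph <- posthoc_pairwise(sel_act$fit, fact)
      .write_csv_checked(
        ph$emmeans[, c(fact, "emmean", "SE", "letters")],
        out("posthoc_activity.csv"), config$force
      )
      report$activity$posthoc <- ph
    }

    stage <- "even-tests"
    later <- obs[obs$timepoint > 1, ]
    agg <- stats::aggregate(
      cbind(arrivals_brown, arrivals_green) ~ Td + Ta + sex, data = later,
      FUN = sum
    )
    agg$p_vs_even <- mapply(test_vs_even, agg$arrivals_brown,
                            agg$arrivals_green)
    agg$prop_brown <- agg$arrivals_brown /
      (agg$arrivals_brown + agg$arrivals_green)
    .write_csv_checked(agg, out("even_tests.csv"), config$force)
    report$even_tests <- agg

    stage <- "manifest"
    outputs <- list.files(config$out_dir, "\\.(csv|json)$")
    outputs <- setdiff(outputs, "manifest.json")
    manifest <- list(
      package = "wingcrypsis",
      version = as.character(utils::packageVersion("wingcrypsis")),
      seed = config$seed, nsim = config$nsim,
      n_wings_per_cell = config$n_wings_per_cell,
      files = as.list(tools::md5sum(file.path(config$out_dir, outputs)))
    )
    names(manifest$files) <- outputs
    .write_checked(out("manifest.json"), function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
    }, config$force)

    .write_checked(out("summary.txt"), function(p) {
      con <- file(p, "w"); on.exit(close(con))
      writeLines(c(
        sprintf("wingcrypsis run (seed %d)", config$seed),
        sprintf("wings scored: %d", report$n_wings),
        sprintf("preference model: %s",
                paste(sel_pref$spec$fixed, collapse = " + ")),
        sprintf("activity model: %s",
                paste(sel_act$spec$fixed, collapse = " + ")),
        sprintf("Td19 coefficient (preference, logit): %s",
                if ("Td19" %in% names(coef(sel_pref$fit)))
                  sprintf("%.3f", coef(sel_pref$fit)[["Td19"]]) else "dropped"),
        sprintf("crypsis-to-brown Td19 shift: %.5f",
                unname(stats::coef(cry_fit)["Td19"]))
      ), con)
    }, config$force)

    report
  }, error = function(e) {
    stop_wc("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
  invisible(report)
}

#' Draw summary figures from pipeline results
#'
#' One figure per analysis: internal contrast by element and treatment,
#' crypsis score by treatment with Tukey letters, and the behavioural
#' probabilities per cohort with letters (and 1:1-test asterisks for
#' preference).  Figures are plain PNG files drawn with base graphics.
#'
#' @param results_dir directory holding [run_full_pipeline()] outputs.
#' @param out_dir where to write the figures (default: `results_dir`).
#' @return character vector of figure paths, invisibly.
#' @export
make_figures <- function(results_dir, out_dir = results_dir) {
  need <- c("scores_contrast.csv", "scores_crypsis.csv", "cohorts.csv")
  for (f in need) {
    if (!file.exists(file.path(results_dir, f))) {
      stop_wc("missing results file: ", f)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctr <- utils::read.csv(file.path(results_dir, "scores_contrast.csv"))
  cry <- utils::read.csv(file.path(results_dir, "scores_crypsis.csv"))
  obs <- utils::read.csv(file.path(results_dir, "cohorts.csv"))
  if (nrow(ctr) == 0 || nrow(cry) == 0 || nrow(obs) == 0) {
    stop_wc("results are empty; nothing to plot")
  }
  paths <- character(0)

  cell_lab <- function(d) paste0("Td", d$Td, ".Ta", d$Ta, ".", d$sex)

  p1 <- file.path(out_dir, "fig_contrast.png")
  grDevices::png(p1, width = 900, height = 500)
  graphics::par(mar = c(9, 4, 2, 1))
  ctr$grp <- interaction(ctr$element, paste0("Td", ctr$Td), sep = " ")
  graphics::boxplot(contrast ~ grp, data = ctr, las = 2,
                    ylab = "contrast to wing background (CIE-xy distance)",
                    main = "Internal contrast by element")
  grDevices::dev.off()
  paths <- c(paths, p1)

  p2 <- file.path(out_dir, "fig_crypsis.png")
  grDevices::png(p2, width = 800, height = 500)
  graphics::par(mar = c(7, 4, 2, 1))
  cry$grp <- factor(cell_lab(cry))
  graphics::stripchart(crypsis_brown ~ grp, data = cry, vertical = TRUE,
                       method = "jitter", pch = 19,
                       col = grDevices::adjustcolor("sienna", 0.6), las = 2,
                       ylab = "crypsis score vs brown patch")
  mns <- tapply(cry$crypsis_brown, cry$grp, mean)
  graphics::points(seq_along(mns), mns, pch = 3, cex = 2)
  ph_path <- file.path(results_dir, "posthoc_crypsis.csv")
  if (file.exists(ph_path)) {
    ph <- utils::read.csv(ph_path)
    ph$grp <- paste0("Td", ph$Td, ".Ta", ph$Ta, ".", ph$Sex)
    lt <- ph$letters[match(levels(cry$grp), ph$grp)]
    graphics::mtext(lt, side = 3, at = seq_along(mns), line = 0)
  }
  grDevices::dev.off()
  paths <- c(paths, p2)

  later <- obs[obs$timepoint > 1, ]
  beh <- function(col_n, col_d, fname, ylab, letters_file = NULL,
                  even_file = NULL) {
    d <- stats::aggregate(later[, c(col_n, col_d)],
                          by = later[, c("cohort_id", "sex", "Td", "Ta")],
                          FUN = sum)
    d$p <- d[[col_n]] / (d[[col_n]] + d[[col_d]])
    d$grp <- factor(cell_lab(d))
    pth <- file.path(out_dir, fname)
    grDevices::png(pth, width = 800, height = 500)
    graphics::par(mar = c(7, 4, 2, 1))
    graphics::stripchart(p ~ grp, data = d, vertical = TRUE,
                         method = "jitter", pch = 19,
                         col = grDevices::adjustcolor("steelblue", 0.6),
                         las = 2, ylim = c(0, 1), ylab = ylab)
    graphics::abline(h = 0.5, lty = 2)
    mns <- tapply(d$p, d$grp, mean)
    graphics::points(seq_along(mns), mns, pch = 3, cex = 2)
    if (!is.null(letters_file) &&
        file.exists(file.path(results_dir, letters_file))) {
      ph <- utils::read.csv(file.path(results_dir, letters_file))
      fcols <- intersect(c("Td", "Ta", "Sex"), names(ph))
      # letters may be over a subset of factors; annotate only if they
      # cover the full cell
      if (length(fcols) == 3) {
        ph$grp <- paste0("Td", ph$Td, ".Ta", ph$Ta, ".", ph$Sex)
        lt <- ph$letters[match(levels(d$grp), ph$grp)]
        graphics::mtext(lt, side = 3, at = seq_along(mns), line = 0)
      }
    }
    if (!is.null(even_file) &&
        file.exists(file.path(results_dir, even_file))) {
      ev <- utils::read.csv(file.path(results_dir, even_file))
      ev$grp <- paste0("Td", ev$Td, ".Ta", ev$Ta, ".", ev$sex)
      star <- ifelse(ev$p_vs_even[match(levels(d$grp), ev$grp)] < 0.05,
                     "*", "")
      graphics::mtext(star, side = 1, at = seq_along(mns), line = -1.2,
                      cex = 1.4)
    }
    grDevices::dev.off()
    pth
  }
  paths <- c(paths,
             beh("arrivals_brown", "arrivals_green", "fig_preference.png",
                 "P(relocate to brown)", "posthoc_preference.csv",
                 "even_tests.csv"),
             beh("relocated", "stationary", "fig_activity.png",
                 "P(relocate)", "posthoc_activity.csv"))
  invisible(paths)
}
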