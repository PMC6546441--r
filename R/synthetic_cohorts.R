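# Synthetic behavioural cohort series.
#
# Emulates the flight-cage assay: cohorts of same-sex butterflies from each
# developmental (Td) x adult (Ta) temperature cell, observed over a series
# of time-lapse photos.  Each photo records how many individuals perch on
# brown vs green patches, how many relocated since the previous photo, and
# where the movers landed.  Preference (arrival to brown vs green) and
# activity (relocated vs stationary) follow logit-linear models in Td, Ta,
# Sex and their two-way interactions, with crossed Gaussian random
# intercepts for cohort and time point.
#
# Bookkeeping model: all individuals are perched at every photo; at each
# step every individual independently relocates with the activity
# probability; movers depart uniformly from the currently perched (a
# hypergeometric split over brown/green) and re-alight on brown with the
# preference probability.  Departures are not described in the source
# protocol; the uniform rule is the simplest one that keeps occupancy,
# arrivals and relocations mutually consistent.

# recognised fixed-effect term names (indicator coding: Td19 = [Td == 19],
# Ta19 = [Ta == 19], SexF = [sex == F]; baseline cell Td27/Ta27/M)
.COHORT_TERMS <- c("intercept", "Td19", "Ta19", "SexF",
                   "Td19:Ta19", "Td19:SexF", "Ta19:SexF")

#' Parameters for the synthetic cohort-series generator
#'
#' Defaults encode the study conditions: 8 cohorts per Td x Ta x Sex cell
#' (16 per temperature treatment, split by sex), 20 individuals per cohort,
#' 15 photos.  Effect sizes on the logit scale follow the qualitative
#' seasonal-crypsis structure — cool-reared (Td 19) individuals prefer brown
#' more, the preference is stronger in females and sharpened at cool test
#' temperatures (Ta:Sex), while activity rises for cool-reared/cool-tested
#' males but not females; magnitudes are set so the treatment effects are
#' clearly detectable at the default design size (see the methods vignette).
#'
#' @param n_cohorts_per_cell cohorts per Td x Ta x Sex cell.
#' @param cohort_size individuals per cohort.
#' @param n_timepoints photos per cohort (>= 2).
#' @param fixed_effects_logit list with named numeric vectors `preference`
#'   and `activity`; allowed names: `r paste(.COHORT_TERMS, collapse=", ")`.
#'   The activity intercept is added on top of
#'   `qlogis(mean_relocations_per_photo / cohort_size)`.
#' @param sigma_cohort,sigma_timepoint random-intercept standard deviations
#'   (>= 0), applied independently to both responses.
#' @param mean_relocations_per_photo expected movers per photo in the
#'   baseline cell.
#' @param seed integer master seed.
#' @return object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_cohorts_per_cell = 8L,
                              cohort_size = 20L,
                              n_timepoints = 15L,
                              fixed_effects_logit = list(
                                preference = c(intercept = 0.2, Td19 = 0.7,
                                               SexF = 1.1, "Ta19:SexF" = 0.6),
                                activity = c(Td19 = 0.45, Ta19 = 0.8,
                                             "Td19:SexF" = -0.45,
                                             "Ta19:SexF" = -0.8)
                              ),
                              sigma_cohort = 0.5,
                              sigma_timepoint = 0.3,
                              mean_relocations_per_photo = 6,
                              seed = 1L) {
  p <- structure(list(
    n_cohorts_per_cell = as.integer(n_cohorts_per_cell),
    cohort_size = as.integer(cohort_size),
    n_timepoints = as.integer(n_timepoints),
    fixed_effects_logit = fixed_effects_logit,
    sigma_cohort = sigma_cohort, sigma_timepoint = sigma_timepoint,
    mean_relocations_per_photo = mean_relocations_per_photo,
    seed = as.integer(seed)
  ), class = "cohort_sim_params")
  validate_cohort_sim_params(p)
  p
}

#' @noRd
validate_cohort_sim_params <- function(p) {
  if (p$cohort_size < 1L) stop_wc("cohort_size must be >= 1")
  if (p$n_timepoints < 2L) stop_wc("n_timepoints must be >= 2")
  if (p$n_cohorts_per_cell < 1L) stop_wc("n_cohorts_per_cell must be >= 1")
  if (p$sigma_cohort < 0 || p$sigma_timepoint < 0) {
    stop_wc("random-intercept sds must be >= 0")
  }
  if (p$mean_relocations_per_photo <= 0 ||
      p$mean_relocations_per_photo >= p$cohort_size) {
    stop_wc("mean_relocations_per_photo must be in (0, cohort_size)")
  }
  for (resp in c("preference", "activity")) {
    fe <- p$fixed_effects_logit[[resp]]
    if (is.null(fe)) next
    bad <- setdiff(names(fe), .COHORT_TERMS)
    if (length(bad)) {
      stop_wc("unknown ", resp, " terms: ", paste(bad, collapse = ", "),
              " (allowed: ", paste(.COHORT_TERMS, collapse = ", "), ")")
    }
  }
  invisible(p)
}

# linear predictor for one response over the cohort design (excl. intercept
# base for activity)
.cohort_eta <- function(fe, design) {
  fe <- fe %||% numeric(0)
  g <- function(nm) if (nm %in% names(fe)) fe[[nm]] else 0
  td <- as.numeric(design$Td == 19)
  ta <- as.numeric(design$Ta == 19)
  sx <- as.numeric(design$sex == "F")
  g("intercept") + g("Td19") * td + g("Ta19") * ta + g("SexF") * sx +
    g("Td19:Ta19") * td * ta + g("Td19:SexF") * td * sx +
    g("Ta19:SexF") * ta * sx
}

#' Generate a synthetic cohort observation table
#'
#' Simulates all cohorts of the full Td x Ta x Sex design over
#' `n_timepoints` photos.  Photo 1 has no previous photo, so its arrival and
#' relocation fields are `NA`.  Occupancy is conserved: every photo's
#' `on_brown + on_green` equals the cohort size, arrivals are exactly the
#' movers' landings, and `stationary + relocated` equals the cohort size.
#'
#' @param params a [cohort_sim_params()] object.
#' @return data.frame with columns `cohort_id`, `sex`, `Td`, `Ta`,
#'   `timepoint`, `on_brown`, `on_green`, `arrivals_brown`,
#'   `arrivals_green`, `stationary`, `relocated`.
#' @export
generate_cohort_series <- function(params) {
  validate_cohort_sim_params(params)
  cells <- expand.grid(Td = c(19, 27), Ta = c(19, 27), sex = c("F", "M"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- cells[rep(seq_len(nrow(cells)), each = params$n_cohorts_per_cell), ]
  design$cohort_id <- sprintf("c%03d", seq_len(nrow(design)))
  ncoh <- nrow(design)
  K <- params$cohort_size
  Tn <- params$n_timepoints

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(params$seed, "cohorts"))

  base_act <- stats::qlogis(params$mean_relocations_per_photo / K)
  eta_pref <- .cohort_eta(params$fixed_effects_logit$preference, design)
  eta_act <- base_act + .cohort_eta(params$fixed_effects_logit$activity, design)

  u_pref <- stats::rnorm(ncoh, 0, params$sigma_cohort)
  u_act <- stats::rnorm(ncoh, 0, params$sigma_cohort)
  v_pref <- stats::rnorm(Tn, 0, params$sigma_timepoint)
  v_act <- stats::rnorm(Tn, 0, params$sigma_timepoint)

  res <- vector("list", Tn)
  on_brown <- stats::rbinom(ncoh, K, inv_logit(eta_pref + u_pref + v_pref[1]))
  res[[1]] <- data.frame(
    design[, c("cohort_id", "sex", "Td", "Ta")], timepoint = 1L,
    on_brown = on_brown, on_green = K - on_brown,
    arrivals_brown = NA_integer_, arrivals_green = NA_integer_,
    stationary = NA_integer_, relocated = NA_integer_
  )
  for (t in 2:Tn) {
    p_act <- inv_logit(eta_act + u_act + v_act[t])
    relocated <- stats::rbinom(ncoh, K, p_act)
    from_brown <- stats::rhyper(ncoh, on_brown, K - on_brown, relocated)
    p_pref <- inv_logit(eta_pref + u_pref + v_pref[t])
    arrivals_brown <- stats::rbinom(ncoh, relocated, p_pref)
    on_brown <- on_brown - from_brown + arrivals_brown
    res[[t]] <- data.frame(
      design[, c("cohort_id", "sex", "Td", "Ta")], timepoint = t,
      on_brown = on_brown, on_green = K - on_brown,
      arrivals_brown = arrivals_brown,
      arrivals_green = relocated - arrivals_brown,
      stationary = K - relocated, relocated = relocated
    )
  }
  out <- do.call(rbind, res)
  out <- out[order(out$cohort_id, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' Write / read a cohort observation table as CSV
#'
#' Schema: `cohort_id,sex,Td,Ta,timepoint,on_brown,on_green,arrivals_brown,`
#' `arrivals_green,stationary,relocated`.
#'
#' @param obs cohort table (as from [generate_cohort_series()]).
#' @param path CSV path.
#' @export
write_cohort_csv <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cohort_id", "sex", "Td", "Ta", "timepoint", "on_brown",
           "on_green", "arrivals_brown", "arrivals_green", "stationary",
           "relocated")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop_wc("cohort CSV missing columns: ",
                            paste(miss, collapse = ", "))
  d
}
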