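# Synthetic cohort generator: tabular SBR/CM cohorts with healthy-control
# age/sex structure, stage-graded striatal deficits, head-to-head tracer
# links and longitudinal decline, plus image rendering through the phantom
# forward model.  Every draw is reproducible from (config, seed).

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Primitive generator regions (side-resolved internally); striatum and
# putamen are voxel-weighted composites of these.
.primitive_regions <- c("caudate", "pre_commissural_putamen",
                        "post_commissural_putamen")

#' Cohort simulation configuration
#'
#' Defaults emulate the study conditions of the reference cohorts: 227
#' healthy controls (sex ratio 137 M / 90 F, ages 30-85, mean 62, sd 11.8)
#' for scale definition, and a 68-subject head-to-head cohort (2 healthy, 66
#' with graded striatal deficits) with 45 longitudinally followed subjects
#' contributing 162 paired scans over 2 years.  Healthy-control regional
#' means, cross-tracer slopes/intercepts and annualized decline default to
#' the published calibration values; the age slope (-0.24 CM/yr) and sex
#' offset (-14.8 CM for males) reproduce the reported 2.4%-per-decade and
#' 14.8% effects, anchored to CM = 100 at age 65 / sex 0.5.
#'
#' @param n_hc Healthy-control cohort size.
#' @param n_h2h Head-to-head cohort size.
#' @param n_h2h_hc Healthy controls within the head-to-head cohort.
#' @param n_longitudinal Head-to-head subjects followed longitudinally.
#' @param age_range,age_mean,age_sd Age distribution (truncated normal).
#' @param p_male Probability of male sex (coded 1; female coded 0).
#' @param hc_mean_sbr Healthy-control mean SBR of the primitive regions.
#' @param w_pre_putamen Voxel-weight of the pre-commissural part within the
#'   putamen composite.
#' @param w_caudate_striatum Voxel-weight of the caudate within the striatum
#'   composite.
#' @param age_slope_cm,sex_offset_cm Age and sex effects on the CM scale.
#' @param subject_cv Between-subject coefficient of variation of the
#'   underlying CM level.
#' @param noise_sd_reference Additive SBR measurement noise sd, reference
#'   tracer.
#' @param noise_sd_second Named per-region additive SBR noise sd for the
#'   second tracer, pinned so that simulated head-to-head regressions land in
#'   a moderate-strong R-squared band.
#' @param tracer_map Per-region slope/intercept linking the second tracer's
#'   true SBR to the reference tracer's true SBR.
#' @param tracer_scale Global image intensity scale per tracer.
#' @param pd_stages Disease-stage template rows sampled for deficit subjects.
#' @param deficit_gradient Anterior-posterior putamen deficit offset applied
#'   to deficit subjects (post-commissural reduced most).
#' @param decline_cm_per_yr Annual CM decline of deficit subjects per
#'   primitive region (healthy controls decline at the age slope).
#' @param visits Longitudinal visit times, years from baseline.
#' @param reference_tracer,second_tracer Tracer ids.
#' @param seed Default integer seed.
#' @return A `cm_cohort_config` list.
#' @export
cohort_config <- function(
    n_hc = 227,
    n_h2h = 68,
    n_h2h_hc = 2,
    n_longitudinal = 45,
    age_range = c(30, 85), age_mean = 62, age_sd = 11.8,
    p_male = 137 / 227,
    hc_mean_sbr = c(caudate = 1.23, pre_commissural_putamen = 1.86,
                    post_commissural_putamen = 1.33),
    w_pre_putamen = 0.5,
    w_caudate_striatum = 0.5068,
    age_slope_cm = -0.24,
    sex_offset_cm = -14.8,
    subject_cv = 0.10,
    noise_sd_reference = 0.10,
    noise_sd_second = c(striatum = 0.40, putamen = 0.55, caudate = 0.25,
                        pre_commissural_putamen = 0.45,
                        post_commissural_putamen = 0.45),
    tracer_map = data.frame(
      region = c("striatum", "putamen", "caudate",
                 "pre_commissural_putamen", "post_commissural_putamen"),
      a = c(1.48, 1.93, 1.14, 1.36, 2.38),
      b = c(0.81, 0.64, 0.79, 0.98, 0.59),
      stringsAsFactors = FALSE),
    tracer_scale = c(ioflupane = 1, av133 = 2.5),
    pd_stages = 2:17,
    deficit_gradient = 0.1,
    decline_cm_per_yr = c(caudate = -3.7, pre_commissural_putamen = -3.8,
                          post_commissural_putamen = -2.3),
    visits = c(0, 1, 2),
    reference_tracer = "ioflupane",
    second_tracer = "av133",
    seed = 1) {
  cfg <- list(n_hc = n_hc, n_h2h = n_h2h, n_h2h_hc = n_h2h_hc,
              n_longitudinal = n_longitudinal,
              age_range = age_range, age_mean = age_mean, age_sd = age_sd,
              p_male = p_male, hc_mean_sbr = hc_mean_sbr,
              w_pre_putamen = w_pre_putamen,
              w_caudate_striatum = w_caudate_striatum,
              age_slope_cm = age_slope_cm, sex_offset_cm = sex_offset_cm,
              cm_intercept = 100 - 65 * age_slope_cm - 0.5 * sex_offset_cm,
              subject_cv = subject_cv,
              noise_sd_reference = noise_sd_reference,
              noise_sd_second = noise_sd_second,
              tracer_map = tracer_map, tracer_scale = tracer_scale,
              pd_stages = pd_stages, deficit_gradient = deficit_gradient,
              decline_cm_per_yr = decline_cm_per_yr, visits = visits,
              reference_tracer = reference_tracer,
              second_tracer = second_tracer, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "cm_cohort_config")
}

validate_config <- function(cfg) {
  if (cfg$n_hc < 1 || cfg$n_h2h < 1)
    stop("cohort sizes must be >= 1", call. = FALSE)
  if (cfg$n_h2h_hc < 0 || cfg$n_h2h_hc > cfg$n_h2h)
    stop("invalid group mix: healthy count outside [0, n]", call. = FALSE)
  if (cfg$noise_sd_reference < 0 || any(cfg$noise_sd_second < 0))
    stop("noise sds must be >= 0", call. = FALSE)
  if (any(cfg$tracer_map$a <= 0))
    stop("true cross-tracer slopes must be positive", call. = FALSE)
  if (any(cfg$hc_mean_sbr <= 0))
    stop("healthy-control mean SBRs must be positive", call. = FALSE)
  invisible(cfg)
}

# Healthy-control mean SBR for any region (primitive or composite).
config_hc_mu <- function(cfg, region) {
  mus <- cfg$hc_mean_sbr
  put <- cfg$w_pre_putamen * mus[["pre_commissural_putamen"]] +
    (1 - cfg$w_pre_putamen) * mus[["post_commissural_putamen"]]
  all_mu <- c(mus, putamen = put,
              striatum = cfg$w_caudate_striatum * mus[["caudate"]] +
                (1 - cfg$w_caudate_striatum) * put)
  unname(all_mu[region])
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# Per-subject primitive deficit fractions by region and side.
subject_fractions <- function(stage, group, gradient) {
  fr <- .template_fractions[stage, ]
  out <- list()
  for (side in c("left", "right")) {
    f_put <- fr[[paste0("putamen_", side)]]
    f_caud <- fr[[paste0("caudate_", side)]]
    if (group == "hc") {
      f_pre <- f_put; f_post <- f_put
    } else {
      f_pre <- min(1, f_put + gradient)
      f_post <- max(0, f_put - gradient)
    }
    out[[side]] <- c(caudate = f_caud, pre_commissural_putamen = f_pre,
                     post_commissural_putamen = f_post)
  }
  out
}

# Truth rows (primitive + composite regions, left/right/bilateral) for one
# subject at one session, given the subject's primitive CM values.
truth_rows_from_primitives <- function(cfg, prim_cm) {
  mus <- cfg$hc_mean_sbr
  rows <- list()
  sbr_side <- list()
  for (side in c("left", "right")) {
    cmv <- prim_cm[[side]]
    sbr <- cmv / 100 * mus[.primitive_regions]
    names(sbr) <- .primitive_regions
    put <- cfg$w_pre_putamen * sbr[["pre_commissural_putamen"]] +
      (1 - cfg$w_pre_putamen) * sbr[["post_commissural_putamen"]]
    str <- cfg$w_caudate_striatum * sbr[["caudate"]] +
      (1 - cfg$w_caudate_striatum) * put
    sbr_side[[side]] <- c(sbr, putamen = put, striatum = str)
  }
  regions <- names(sbr_side$left)
  bilat <- (sbr_side$left + sbr_side$right) / 2
  out <- rbind(
    data.frame(region = regions, side = "left",
               true_sbr = unname(sbr_side$left)),
    data.frame(region = regions, side = "right",
               true_sbr = unname(sbr_side$right)),
    data.frame(region = regions, side = "bilateral",
               true_sbr = unname(bilat)))
  out$true_cm <- 100 * out$true_sbr / config_hc_mu(cfg, out$region)
  out
}

#' Simulate a tabular cohort with known ground truth
#'
#' Draws subjects with age/sex structure imposed on the Centamine scale and
#' mapped back to SBR through the healthy-control anchors; deficit subjects
#' receive stage-graded striatal reductions with the post-commissural putamen
#' reduced most and the caudate least.  Observed SBR values add independent
#' Gaussian measurement noise to the truth.  Deterministic under
#' (config, seed).
#'
#' @param config A [cohort_config()].
#' @param cohort "hc" (scale-definition cohort, all healthy) or "h2h"
#'   (head-to-head style mix of healthy and deficit subjects).
#' @param n Cohort size override.
#' @param seed Seed override (default `config$seed`).
#' @return A `cm_simulation`: `sbr` (observed long-format SBR table for the
#'   reference tracer), `subjects`, `truth` (per subject/session/region/side
#'   true SBR and CM), and the `config`.
#' @export
simulate_cohort <- function(config, cohort = c("hc", "h2h"), n = NULL,
                            seed = config$seed) {
  stopifnot(inherits(config, "cm_cohort_config"))
  cohort <- match.arg(cohort)
  if (is.null(n)) n <- if (cohort == "hc") config$n_hc else config$n_h2h
  with_local_seed(seed, {
    n_hc <- if (cohort == "hc") n else min(config$n_h2h_hc, n)
    group <- c(rep("hc", n_hc), rep("pd", n - n_hc))
    subjects <- data.frame(
      subject = sprintf("%s%03d", toupper(substr(cohort, 1, 1)), seq_len(n)),
      group = group,
      stage = ifelse(group == "hc", 1L,
                     sample(config$pd_stages, n, replace = TRUE)),
      age = rtruncnorm1(n, config$age_mean, config$age_sd,
                        config$age_range[1], config$age_range[2]),
      sex = as.numeric(stats::rbinom(n, 1, config$p_male)),
      stringsAsFactors = FALSE)
    subjects$cm_base <- (config$age_slope_cm * subjects$age +
                           config$sex_offset_cm * subjects$sex +
                           config$cm_intercept) *
      pmax(0.2, 1 + stats::rnorm(n) * config$subject_cv)

    truth <- vector("list", n)
    for (i in seq_len(n)) {
      fr <- subject_fractions(subjects$stage[i], subjects$group[i],
                              config$deficit_gradient)
      prim_cm <- lapply(fr, function(f) subjects$cm_base[i] * f)
      tr <- truth_rows_from_primitives(config, prim_cm)
      truth[[i]] <- data.frame(subject = subjects$subject[i],
                               tracer = config$reference_tracer,
                               session_years = 0,
                               age = subjects$age[i], sex = subjects$sex[i],
                               tr, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    sbr <- truth[, c("subject", "tracer", "session_years", "age", "sex",
                     "region", "side")]
    sbr$value <- truth$true_sbr +
      stats::rnorm(nrow(truth), sd = config$noise_sd_reference)
    structure(list(sbr = sbr, subjects = subjects, truth = truth,
                   config = config, cohort = cohort),
              class = "cm_simulation")
  })
}

#' @export
print.cm_simulation <- function(x, ...) {
  cat(sprintf("<cm_simulation> %d subjects (%s), %d sessions, tracer(s): %s\n",
              nrow(x$subjects), x$cohort,
              length(unique(paste(x$sbr$subject, x$sbr$session_years))),
              paste(unique(x$sbr$tracer), collapse = ", ")))
  invisible(x)
}

#' Add longitudinal visits with linear Centamine decline
#'
#' The first `n_longitudinal` subjects receive repeat sessions at the
#' configured visit times (the first four of them one extra visit, matching
#' the 162-paired-scan layout at the defaults); each deficit subject's
#' primitive-region CM declines linearly at the configured per-region rate,
#' healthy controls at the age slope.  Observation noise is redrawn per
#' visit.
#'
#' @param sim A `cm_simulation` from [simulate_cohort()].
#' @param config Configuration (default: the simulation's).
#' @param seed Seed for the new noise draws.
#' @return The extended `cm_simulation`.
#' @export
simulate_longitudinal <- function(sim, config = sim$config,
                                  seed = config$seed + 1L) {
  stopifnot(inherits(sim, "cm_simulation"))
  if (any(config$visits < 0))
    stop("visit times must be nonnegative years from baseline",
         call. = FALSE)
  visits <- sort(unique(config$visits))
  if (length(visits) < 2L)
    stop("need at least 2 visit times", call. = FALSE)
  n_long <- min(config$n_longitudinal, nrow(sim$subjects))
  extra4 <- seq_len(min(4L, n_long))
  with_local_seed(seed, {
    base <- sim$truth[sim$truth$session_years == 0, , drop = FALSE]
    new_truth <- list(base)
    for (i in seq_len(n_long)) {
      subj <- sim$subjects$subject[i]
      is_pd <- sim$subjects$group[i] == "pd"
      tv <- if (i %in% extra4) {
        seq(min(visits), max(visits), length.out = length(visits) + 1L)
      } else visits
      tv <- setdiff(tv, 0)
      b <- base[base$subject == subj, , drop = FALSE]
      prim_rate <- if (is_pd) config$decline_cm_per_yr else
        stats::setNames(rep(config$age_slope_cm, 3), .primitive_regions)
      for (t in tv) {
        bt <- b
        bt$session_years <- t
        bt$age <- bt$age + t
        for (side in c("left", "right")) {
          wh <- which(bt$side == side)
          cm0 <- stats::setNames(
            bt$true_cm[wh][match(.primitive_regions, bt$region[wh])],
            .primitive_regions)
          cm_t <- cm0 + prim_rate[.primitive_regions] * t
          tr <- truth_rows_from_primitives(
            config, list(left = cm_t, right = cm_t))
          # recompute only this side's rows from its own primitives
          tr <- tr[tr$side == "left", , drop = FALSE]
          ix <- match(tr$region, bt$region[wh])
          bt$true_sbr[wh[ix]] <- tr$true_sbr
          bt$true_cm[wh[ix]] <- tr$true_cm
        }
        bi <- bt$side == "bilateral"
        for (r in unique(bt$region)) {
          l <- bt$true_sbr[bt$side == "left" & bt$region == r]
          rr <- bt$true_sbr[bt$side == "right" & bt$region == r]
          bt$true_sbr[bi & bt$region == r] <- (l + rr) / 2
          bt$true_cm[bi & bt$region == r] <-
            100 * (l + rr) / 2 / config_hc_mu(config, r)
        }
        new_truth <- c(new_truth, list(bt))
      }
    }
    truth <- do.call(rbind, new_truth)
    truth <- truth[order(truth$subject, truth$session_years), , drop = FALSE]
    rownames(truth) <- NULL
    sbr <- truth[, c("subject", "tracer", "session_years", "age", "sex",
                     "region", "side")]
    sbr$value <- truth$true_sbr +
      stats::rnorm(nrow(truth), sd = config$noise_sd_reference)
    out <- sim
    out$sbr <- sbr
    out$truth <- truth
    out
  })
}

#' Add paired second-tracer measurements
#'
#' For every session of the reference tracer, the second tracer's true SBR in
#' the primitive regions (caudate, pre- and post-commissural putamen) is the
#' configured per-region linear transform of the reference tracer's *true*
#' SBR; putamen and striatum truths are the voxel-weighted combinations of
#' those primitives, keeping the tabular truth consistent with images painted
#' at subregion level.  Observations add independent per-region Gaussian
#' noise.  Paired on (subject, session).
#'
#' @param sim A `cm_simulation` containing the reference tracer.
#' @param config Configuration (default: the simulation's).
#' @param seed Seed for the second tracer's noise.
#' @return The `cm_simulation` with both tracers in `sbr` and `truth`.
#' @export
simulate_head2head <- function(sim, config = sim$config,
                               seed = config$seed + 2L) {
  stopifnot(inherits(sim, "cm_simulation"))
  ref <- sim$truth[sim$truth$tracer == config$reference_tracer, ,
                   drop = FALSE]
  if (!nrow(ref))
    stop("simulation does not contain the reference tracer", call. = FALSE)
  map <- config$tracer_map
  i <- match(ref$region, map$region)
  if (anyNA(i))
    stop("missing tracer mapping for region(s): ",
         paste(unique(ref$region[is.na(i)]), collapse = ", "), call. = FALSE)
  with_local_seed(seed, {
    y <- ref
    y$tracer <- config$second_tracer
    y$true_sbr <- map$a[i] * ref$true_sbr + map$b[i]
    # composites: voxel-weighted combinations of the primitive-region values
    key <- paste(y$subject, y$session_years, y$side)
    val <- function(region) {
      sel <- y$region == region
      stats::setNames(y$true_sbr[sel], key[sel])[key]
    }
    put <- config$w_pre_putamen * val("pre_commissural_putamen") +
      (1 - config$w_pre_putamen) * val("post_commissural_putamen")
    str <- config$w_caudate_striatum * val("caudate") +
      (1 - config$w_caudate_striatum) * put
    y$true_sbr[y$region == "putamen"] <- put[y$region == "putamen"]
    y$true_sbr[y$region == "striatum"] <- str[y$region == "striatum"]
    # harmonized scale: true CM carries over from the reference tracer
    sd_y <- config$noise_sd_second[ref$region]
    if (anyNA(sd_y))
      stop("missing second-tracer noise sd for region(s): ",
           paste(unique(ref$region[is.na(sd_y)]), collapse = ", "),
           call. = FALSE)
    obs <- y[, c("subject", "tracer", "session_years", "age", "sex",
                 "region", "side")]
    obs$value <- y$true_sbr + stats::rnorm(nrow(y), sd = sd_y)
    out <- sim
    out$sbr <- rbind(sim$sbr, obs)
    out$truth <- rbind(sim$truth, y)
    out
  })
}

#' Render phantom images for simulated sessions
#'
#' Bridges the tabular truth to the image level: for each requested
#' (subject, session, tracer) the primitive-region true SBR values are
#' painted into the caudate/putamen subregions (value = 1 + SBR relative to
#' the white-matter reference), all other regions keep the healthy-control
#' defaults, and the scan is synthesized through the forward model with a
#' per-scan random misalignment affine, a per-tracer global intensity scale,
#' and optional voxel noise.
#'
#' @param sim A `cm_simulation`.
#' @param bank A `cm_template_bank` (its atlas defines the grid).
#' @param tracers Tracers to render (default: all in the truth table).
#' @param subjects Subjects to render (default: all).
#' @param max_translation_mm,max_rotation_deg,scale_range Misalignment
#'   bounds; draws are uniform within them (shears are not simulated).
#' @param noise_sd Voxelwise Gaussian noise sd.
#' @param seed Seed for misalignments and noise.
#' @return A list with `scans` (one entry per rendered session: `volume`,
#'   metadata and `truth` with the exact painted values and affine) and
#'   `meta` (a data frame of the metadata).
#' @export
render_images <- function(sim, bank, tracers = NULL, subjects = NULL,
                          max_translation_mm = 8, max_rotation_deg = 8,
                          scale_range = c(0.95, 1.05), noise_sd = 0,
                          seed = sim$config$seed + 3L) {
  stopifnot(inherits(sim, "cm_simulation"),
            inherits(bank, "cm_template_bank"))
  cfg <- sim$config
  atlas <- bank$atlas
  truth <- sim$truth
  if (is.null(tracers)) tracers <- unique(truth$tracer)
  if (is.null(subjects)) subjects <- unique(truth$subject)
  keys <- unique(truth[truth$tracer %in% tracers &
                         truth$subject %in% subjects,
                       c("subject", "tracer", "session_years", "age", "sex")])
  rownames(keys) <- NULL
  prim_to_codes <- list(
    caudate = c("pre_caudate", "post_caudate"),
    pre_commissural_putamen = c("pre_dorsal_putamen", "pre_ventral_putamen"),
    post_commissural_putamen = c("post_dorsal_putamen",
                                 "post_ventral_putamen"))
  rt <- atlas$region_table
  with_local_seed(seed, {
    scans <- vector("list", nrow(keys))
    for (k in seq_len(nrow(keys))) {
      row <- keys[k, ]
      values <- bank$hc_values
      for (side in c("left", "right")) {
        sel <- truth$subject == row$subject & truth$tracer == row$tracer &
          truth$session_years == row$session_years & truth$side == side
        for (pr in .primitive_regions) {
          s <- truth$true_sbr[sel & truth$region == pr]
          if (!length(s))
            stop("missing true SBR for ", pr, " (", side, ") of subject ",
                 row$subject, call. = FALSE)
          codes <- rt$code[rt$name %in% prim_to_codes[[pr]] &
                             rt$side == side]
          values[as.character(codes)] <- 1 + s
        }
      }
      scl <- unname(cfg$tracer_scale[row$tracer])
      if (is.na(scl)) scl <- 1
      tfm <- affine_transform(
        translation = stats::runif(3, -max_translation_mm,
                                   max_translation_mm),
        rotation = stats::runif(3, -max_rotation_deg, max_rotation_deg) *
          pi / 180,
        scale = stats::runif(3, scale_range[1], scale_range[2]))
      syn <- synthesize_scan(bank, values = values, scale = scl,
                             noise_sd = noise_sd, transform = tfm)
      scans[[k]] <- list(volume = syn$volume, subject = row$subject,
                         tracer = row$tracer,
                         session_years = row$session_years,
                         age = row$age, sex = row$sex,
                         truth = list(values = values, transform = tfm,
                                      scale = scl, noise_sd = noise_sd))
    }
    list(scans = scans, meta = keys)
  })
}
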