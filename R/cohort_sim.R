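#' Parameters of the simulated volumetry cohort
#'
#' The simulator emulates the statistical structure of a two-rater manual
#' hippocampal volumetry study: volumes follow an inverted-U quadratic law
#' over age (defaults pass through the peak of 3.7 cm^3 at age 55 and
#' 1.7 cm^3 at age 90), men run higher than women by `sex_offset`, right
#' hippocampi higher than left by `hemisphere_offset`, and the second
#' rater's measurement is a linear recalibration of the first's
#' (`rater2_slope * v + rater2_intercept`) plus calibration noise.
#'
#' When `rater2_noise_sd` is `NULL` it is derived from a target coefficient
#' of determination via [calibration_noise_sd()], so the rater-2 regression
#' has the requested R^2 in expectation given the configured rater-1
#' variance.
#'
#' @param n_patients number of patients (>= 1).
#' @param age_range length-2 years, ages drawn uniformly (default 18-95).
#' @param peak_age,peak_volume vertex of the quadratic volume-age law
#'   (years, cm^3).
#' @param end_age,end_volume a second anchor point of the quadratic (the
#'   end-of-decline volume), default 1.7 cm^3 at 90 years.
#' @param p_male probability a patient is male (default 26/63).
#' @param sex_offset male minus female volume offset, cm^3.
#' @param hemisphere_offset right minus left volume offset, cm^3.
#' @param residual_sd per-measurement volume noise, cm^3.
#' @param rater2_slope,rater2_intercept rater-2 calibration line.
#' @param rater2_r2 target R^2 of the rater-2 on rater-1 regression; used
#'   only when `rater2_noise_sd` is `NULL`.
#' @param rater2_noise_sd calibration noise sd, cm^3 (`NULL` = derive from
#'   `rater2_r2`).
#' @param descriptor_means,descriptor_sds named means / spreads for the
#'   non-volume descriptors (`aspect_ratio`, `diameter_cm`, `roundness`,
#'   `sphericity`, `vs_ratio`).
#' @param diameter_volume_link if `TRUE` (default) the diameter scales with
#'   the cube root of volume, as it must for geometrically similar solids.
#' @param seed integer seed making the draw reproducible.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 63,
                              age_range = c(18, 95),
                              peak_age = 55, peak_volume = 3.7,
                              end_age = 90, end_volume = 1.7,
                              p_male = 26 / 63,
                              sex_offset = 0.14,
                              hemisphere_offset = 0.325,
                              residual_sd = 0.3,
                              rater2_slope = 0.981,
                              rater2_intercept = 0.156,
                              rater2_r2 = 0.93,
                              rater2_noise_sd = NULL,
                              descriptor_means = c(aspect_ratio = 0.28,
                                                   diameter_cm = 4.03,
                                                   roundness = 0.75,
                                                   sphericity = 0.12,
                                                   vs_ratio = 7.93),
                              descriptor_sds = c(aspect_ratio = 0.03,
                                                 diameter_cm = 0.20,
                                                 roundness = 0.05,
                                                 sphericity = 0.02,
                                                 vs_ratio = 0.60),
                              diameter_volume_link = TRUE,
                              seed = 1L) {
  if (n_patients < 1) stop("`n_patients` must be >= 1")
  if (peak_age < age_range[1] || peak_age > age_range[2])
    stop("`peak_age` must lie within `age_range`")
  if (residual_sd < 0 || (!is.null(rater2_noise_sd) && rater2_noise_sd < 0) ||
      any(descriptor_sds < 0))
    stop("spreads must be >= 0")
  if (end_age == peak_age) stop("`end_age` must differ from `peak_age`")
  p <- structure(as.list(environment()), class = "cohort_sim_params")
  if (is.null(p$rater2_noise_sd))
    p$rater2_noise_sd <- calibration_noise_sd(p)
  p
}

# quadratic volume-age law fixed by the vertex and one more anchor
volume_age_law <- function(params) {
  k <- (params$end_volume - params$peak_volume) /
       (params$end_age - params$peak_age)^2
  function(age) params$peak_volume + k * (age - params$peak_age)^2
}

#' Theoretical rater-1 volume variance and the derived calibration noise
#'
#' Under the simulator the rater-1 volume is `q(A) + sex + hemisphere +
#' noise` with `A` uniform on the age range, so its variance decomposes as
#' `Var(q(A)) + p(1-p) * sex_offset^2 + hemisphere_offset^2 / 4 +
#' residual_sd^2`; `Var(q(A))` follows from the closed-form uniform moments
#' of `(A - peak_age)^2`. For an ordinary regression of rater 2 on rater 1,
#' `R^2 = slope^2 Var(v1) / (slope^2 Var(v1) + sigma_c^2)`, hence the
#' calibration noise that yields a target R^2 is
#' `sigma_c = |slope| * sd(v1) * sqrt((1 - R2) / R2)`.
#'
#' @param params a [cohort_sim_params()] (the `rater2_noise_sd` field is
#'   ignored here).
#' @return calibration noise standard deviation, cm^3.
#' @export
calibration_noise_sd <- function(params) {
  lo <- params$age_range[1] - params$peak_age
  hi <- params$age_range[2] - params$peak_age
  mom <- function(m) (hi^(m + 1) - lo^(m + 1)) / ((m + 1) * (hi - lo))
  k <- (params$end_volume - params$peak_volume) /
       (params$end_age - params$peak_age)^2
  var_age <- k^2 * (mom(4) - mom(2)^2)
  var1 <- var_age +
    params$p_male * (1 - params$p_male) * params$sex_offset^2 +
    params$hemisphere_offset^2 / 4 +
    params$residual_sd^2
  r2 <- params$rater2_r2
  abs(params$rater2_slope) * sqrt(var1) * sqrt((1 - r2) / r2)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a two-rater cohort descriptor table
#'
#' Produces one record per patient x hemisphere x rater
#' (`n_patients * 2 * 2` rows). Rater-1 volumes follow the configured
#' quadratic age law plus sex and hemisphere offsets and Gaussian noise,
#' truncated below at 0.5 cm^3 (offsets are applied centred, so the
#' quadratic law is the cohort mean curve while group contrasts equal the
#' configured offsets exactly); rater-2 volumes are the linear
#' recalibration of rater 1 plus calibration noise. Non-volume descriptors
#' are drawn around their configured means; by default the diameter scales
#' with the cube root of the record's volume (geometric similarity), the
#' others are independent of volume.
#'
#' @param params a [cohort_sim_params()].
#' @return A `data.frame` (class `cohort_table`) with columns `patient_id`,
#'   `age`, `sex` (M/F), `hemisphere` (L/R), `rater` (1/2), `volume_cm3`,
#'   `aspect_ratio`, `diameter_cm`, `roundness`, `sphericity`, `vs_ratio`.
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  law <- volume_age_law(params)
  with_seed(params$seed, {
    n <- params$n_patients
    age <- stats::runif(n, params$age_range[1], params$age_range[2])
    sex <- ifelse(stats::runif(n) < params$p_male, "M", "F")
    tab <- expand.grid(hemisphere = c("L", "R"), patient_id = seq_len(n),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- tab[, c("patient_id", "hemisphere")]
    tab$age <- age[tab$patient_id]
    tab$sex <- sex[tab$patient_id]
    v1 <- law(tab$age) +
      params$sex_offset * ((tab$sex == "M") - params$p_male) +
      params$hemisphere_offset * ((tab$hemisphere == "R") - 0.5) +
      stats::rnorm(nrow(tab), sd = params$residual_sd)
    v1 <- pmax(v1, 0.5)
    v2 <- params$rater2_slope * v1 + params$rater2_intercept +
      stats::rnorm(nrow(tab), sd = params$rater2_noise_sd)
    v2 <- pmax(v2, 0.5)
    out <- rbind(cbind(tab, rater = 1L, volume_cm3 = v1),
                 cbind(tab, rater = 2L, volume_cm3 = v2))
    m <- params$descriptor_means
    s <- params$descriptor_sds
    nr <- nrow(out)
    draw <- function(key) {
      if (s[[key]] > 0) stats::rnorm(nr, m[[key]], s[[key]]) else rep(m[[key]], nr)
    }
    out$aspect_ratio <- pmax(draw("aspect_ratio"), 1e-3)
    if (params$diameter_volume_link) {
      vbar <- mean(out$volume_cm3)
      base <- m[["diameter_cm"]] * (out$volume_cm3 / vbar)^(1 / 3)
      jit <- if (s[["diameter_cm"]] > 0)
        stats::rnorm(nr, 0, s[["diameter_cm"]]) else 0
      out$diameter_cm <- pmax(base + jit, 1e-3)
    } else {
      out$diameter_cm <- pmax(draw("diameter_cm"), 1e-3)
    }
    out$roundness <- pmin(pmax(draw("roundness"), 1e-3), 1.05)
    out$sphericity <- pmin(pmax(draw("sphericity"), 1e-3), 1)
    out$vs_ratio <- pmax(draw("vs_ratio"), 1e-3)
    out <- out[order(out$patient_id, out$hemisphere, out$rater), ]
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
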