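#' Roster specification for synthetic crews
#'
#' Defines how a crew's statures are drawn: a fixed list, a uniform band, or
#' a truncated normal.  Shared physiological parameters (BMI, age, VO2max,
#' resting VO2, RERs) apply to every member, matching the homogeneous
#' reference populations the model studies.
#'
#' @param n_crew Number of crew members (>= 1).
#' @param sampler One of `"fixed"`, `"uniform"`, `"truncnorm"`.
#' @param statures Stature vector (m) for the `"fixed"` sampler; recycled or
#'   truncated to `n_crew`.
#' @param lo,hi Stature bounds (m) for the stochastic samplers.
#' @param mean,sd Parameters of the `"truncnorm"` sampler.
#' @param seed Integer RNG seed; identical seeds give identical rosters.
#' @param shared_params Named list overriding [crew_member()] defaults
#'   (e.g. `list(bmi = 27)`).
#' @return An object of class `roster_spec`.
#' @export
roster_spec <- function(n_crew = 4,
                        sampler = c("fixed", "uniform", "truncnorm"),
                        statures = rep(1.70, n_crew),
                        lo = 1.50, hi = 1.90,
                        mean = 1.70, sd = 0.07,
                        seed = 1L,
                        shared_params = list()) {
  sampler <- match.arg(sampler)
  if (!is.numeric(n_crew) || n_crew < 1 || n_crew != round(n_crew)) {
    stop_domain("n_crew", "must be a positive integer")
  }
  if (lo >= hi) stop_domain("lo", "must be below hi")
  if (lo < AGENCY_STATURE_BAND[1] || hi > AGENCY_STATURE_BAND[2]) {
    warning(sprintf(
      "sampler bounds [%.3f, %.3f] extend outside the agency stature band [%.3f, %.3f]",
      lo, hi, AGENCY_STATURE_BAND[1], AGENCY_STATURE_BAND[2]
    ), call. = FALSE)
  }
  structure(
    list(
      n_crew = as.integer(n_crew),
      sampler = sampler,
      statures = statures,
      lo = lo, hi = hi, mean = mean, sd = sd,
      seed = as.integer(seed),
      shared_params = shared_params
    ),
    class = "roster_spec"
  )
}

# internal: run expr under a local RNG seed, restoring global state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a crew roster
#'
#' Draws statures according to the roster specification and derives a full
#' [crew_member()] for each.  Deterministic under a fixed seed; sampled
#' statures always fall inside `[lo, hi]`.
#'
#' @param spec A [roster_spec()].
#' @return A list of [crew_member()] objects of length `spec$n_crew`.
#' @examples
#' generate_roster(roster_spec(4, statures = rep(1.50, 4)))
#' @export
generate_roster <- function(spec) {
  stopifnot(inherits(spec, "roster_spec"))
  statures <- switch(
    spec$sampler,
    fixed = rep_len(spec$statures, spec$n_crew),
    uniform = with_local_seed(
      spec$seed,
      stats::runif(spec$n_crew, spec$lo, spec$hi)
    ),
    truncnorm = with_local_seed(spec$seed, {
      # inverse-CDF truncated normal: exact, no rejection loop
      plo <- stats::pnorm(spec$lo, spec$mean, spec$sd)
      phi <- stats::pnorm(spec$hi, spec$mean, spec$sd)
      stats::qnorm(stats::runif(spec$n_crew, plo, phi), spec$mean, spec$sd)
    })
  )
  lapply(statures, function(s) {
    do.call(crew_member, c(list(stature = s), spec$shared_params))
  })
}

#' Reference scenario grid
#'
#' The 5 statures x 6 durations x {no-exercise, ISS-like exercise} grid of
#' four-person homogeneous crews used by the report tables and figure
#' series: statures 1.50--1.90 m in 0.10 m steps; durations 30, 90, 180,
#' 360, 720 and 1,080 d.
#'
#' @param environment A [cabin_environment()] shared by all scenarios.
#' @return A list of 60 [mission_scenario()] objects, each carrying
#'   `stature` and `exercise` attributes.
#' @export
reference_grid <- function(environment = cabin_environment()) {
  presc <- exercise_prescription()
  grid <- list()
  for (stature in REFERENCE_STATURES) {
    roster <- replicate(REFERENCE_CREW_SIZE, crew_member(stature), simplify = FALSE)
    for (duration in REFERENCE_DURATIONS) {
      for (exercise in c(FALSE, TRUE)) {
        sc <- mission_scenario(
          roster, duration,
          prescription = if (exercise) presc else NULL,
          environment = environment
        )
        attr(sc, "stature") <- stature
        attr(sc, "exercise") <- exercise
        grid[[length(grid) + 1]] <- sc
      }
    }
  }
  grid
}
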