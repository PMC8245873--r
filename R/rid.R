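#' A theoretical subject for RID simulation
#'
#' Bundles one subject's compartmental system with the plasma retinol pool
#' size `M5` and derives the assigned (true) total body stores from the
#' steady-state mass solution anchored at `M5`.
#'
#' @param id subject identifier.
#' @param group `"adult"` or `"child"`.
#' @param system a [compartmental_system()] with plasma and storage roles.
#' @param M5 plasma retinol pool size, micromoles (> 0).
#' @return A `subject_spec`: list with `id`, `group`, `system`, `M5`,
#'   `assigned_tbs`, `masses` (the full steady state) and `intake`.
#' @export
subject_spec <- function(id, group = c("adult", "child"), system, M5) {
  group <- match.arg(group)
  stopifnot(inherits(system, "compartmental_system"))
  if (is.null(system$plasma) || is.null(system$storage)) {
    stop("subject systems need plasma and storage roles", call. = FALSE)
  }
  if (!is.finite(M5) || M5 <= 0) stop("M5 must be > 0", call. = FALSE)
  st <- steady_state_masses(system, M5 = M5)
  tbs <- assigned_tbs(st, system)
  if (tbs <= 0) stop("assigned TBS must be > 0", call. = FALSE)
  structure(
    list(id = as.character(id), group = group, system = system, M5 = M5,
         assigned_tbs = tbs, masses = st$masses, intake = st$intake),
    class = "subject_spec"
  )
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("<subject_spec %s (%s): M5 = %.3g umol, TBS = %.4g umol>\n",
              x$id, x$group, x$M5, x$assigned_tbs))
  invisible(x)
}

#' RID equation terms along a tracer time course
#'
#' Computes, at every time of a solved tracer time course, the terms of
#' the retinol isotope dilution prediction equation
#' \deqn{TBS = Fa \times S \times 1/SA_p}
#' where `Fa` is the fraction of dose in the two storage compartments,
#' `SAp = FDp / M5` is plasma retinol specific activity (fraction of dose
#' per micromole, with `FDp` the fraction of dose in plasma),
#' `SAs = Fa / TBS` is the specific activity of the stores, `S = SAp/SAs`,
#' and `FaS = Fa * S` is the composite coefficient multiplying `1/SAp`.
#'
#' At times before any tracer has reached the stores (`Fa = 0`, e.g. the
#' instant of dosing) `SAs`, `S` and `FaS` are undefined; they are
#' returned as `NA` and the affected times are recorded in the
#' `masked_times` attribute rather than silently propagating NaN.
#'
#' @param tc a `tracer_timecourse` solved on `subject$system`.
#' @param subject a [subject_spec()].
#' @return A data frame of class `rid_trajectory` with columns `day`,
#'   `Fa`, `FDp`, `SAp`, `SAs`, `S`, `FaS`.
#' @export
rid_quantities <- function(tc, subject) {
  stopifnot(inherits(tc, "tracer_timecourse"),
            inherits(subject, "subject_spec"))
  sys <- subject$system
  if (ncol(tc$q) != sys$n) {
    stop("time course does not match subject's system", call. = FALSE)
  }
  Fa <- rowSums(tc$q[, sys$storage, drop = FALSE])
  FDp <- tc$q[, sys$plasma]
  SAp <- FDp / subject$M5
  SAs <- Fa / subject$assigned_tbs
  defined <- Fa > 0
  S <- ifelse(defined, SAp / SAs, NA_real_)
  FaS <- ifelse(defined, Fa * S, NA_real_)
  out <- data.frame(day = tc$times, Fa = Fa, FDp = FDp,
                    SAp = SAp, SAs = SAs, S = S, FaS = FaS)
  attr(out, "masked_times") <- tc$times[!defined]
  attr(out, "subject_id") <- subject$id
  class(out) <- c("rid_trajectory", "data.frame")
  out
}

#' Predict total body stores by the RID equation
#'
#' `TBS = FaS / SAp`, i.e. the composite coefficient `Fa * S` divided by
#' the measured plasma retinol specific activity. When a subject's own
#' `FaS` and `SAp` at the same time are used, the prediction returns the
#' assigned TBS identically; in practice a group (geometric-mean) `FaS` is
#' combined with each individual's measured `SAp`.
#'
#' @param fas_coefficient composite coefficient `Fa * S` (dimensionless,
#'   > 0).
#' @param sap plasma retinol specific activity, fraction of dose per
#'   micromole (> 0). Vectors are recycled as usual.
#' @return predicted TBS, micromoles.
#' @export
#' @examples
#' predict_tbs(0.5, 0.005)  # 100 umol
predict_tbs <- function(fas_coefficient, sap) {
  if (any(!is.finite(fas_coefficient)) || any(fas_coefficient <= 0)) {
    stop("`fas_coefficient` must be positive", call. = FALSE)
  }
  if (any(!is.finite(sap)) || any(sap <= 0)) {
    stop("`sap` must be positive", call. = FALSE)
  }
  fas_coefficient / sap
}

#' RID trajectories for a whole cohort
#'
#' Solves the tracer model for every subject and stacks the RID terms into
#' one long table, the common input for the cohort summaries.
#'
#' @param subjects list of [subject_spec()] objects.
#' @param days integer days at which the terms are reported (default
#'   1 to 30; day 0 is always simulated internally).
#' @return data frame with columns `subject_id`, `group`, `day`, `Fa`,
#'   `FDp`, `SAp`, `SAs`, `S`, `FaS`; assigned TBS and M5 per subject are
#'   attached as the `assigned` attribute (data frame `subject_id`,
#'   `group`, `M5`, `assigned_tbs`).
#' @export
cohort_rid <- function(subjects, days = 1:30) {
  stopifnot(length(subjects) >= 1)
  days <- sort(unique(as.integer(days)))
  times <- if (days[1] == 0) days else c(0L, days)
  rows <- lapply(subjects, function(s) {
    tc <- solve_tracer(s$system, times = times)
    tr <- rid_quantities(tc, s)
    tr <- tr[tr$day %in% days, , drop = FALSE]
    cbind(subject_id = s$id, group = s$group, tr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "assigned") <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "id"),
    group = vapply(subjects, `[[`, character(1), "group"),
    M5 = vapply(subjects, `[[`, numeric(1), "M5"),
    assigned_tbs = vapply(subjects, `[[`, numeric(1), "assigned_tbs")
  )
  out
}
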