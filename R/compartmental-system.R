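#' Linear compartmental tracer system
#'
#' Constructs and validates a linear, constant-coefficient compartmental
#' model of whole-body vitamin A kinetics. The system is described by
#' fractional transfer coefficients `L(i,j)` (fraction of compartment `j`'s
#' content moving to compartment `i` per day) and irreversible-loss
#' coefficients `L(0,j)`. Compartment roles identify where the oral tracer
#' dose enters (`dosing`), the plasma retinol compartment (`plasma`), and
#' the two vitamin A storage compartments (`storage`) whose summed tracee
#' mass defines total body stores (TBS).
#'
#' An optional absorptive delay is modeled as a chain of first-order
#' stages with total mean transit time `delay$duration` days; the dose (and
#' dietary intake) passes through the chain before reaching the dosing
#' compartment. A fraction `1 - absorption_fraction` of the dose is never
#' absorbed and is routed directly to irreversible loss at time zero, so
#' that mass balance always sums to one.
#'
#' @param transfer numeric `n x n` matrix of fractional transfer
#'   coefficients, `transfer[i, j] = L(i,j)` in 1/day; the diagonal must be
#'   zero (outflow is implied by the off-diagonal entries and `loss`).
#' @param loss numeric vector of length `n`, `loss[j] = L(0,j)` in 1/day.
#' @param dosing index of the compartment receiving the absorbed dose.
#' @param plasma index of the plasma retinol compartment, or `NULL` when
#'   the system is not used for RID calculations.
#' @param storage integer vector of exactly two storage-compartment
#'   indices, or `NULL`.
#' @param delay `NULL`, or `list(duration = days, stages = count)`.
#' @param absorption_fraction fraction of the oral dose absorbed, in
#'   (0, 1].
#'
#' @return An object of class `compartmental_system`.
#'
#' @details The state matrix `A` has `A[i,j] = L(i,j)` off the diagonal and
#'   `A[j,j] = -(sum_i L(i,j) + L(0,j))`. The system must be open: every
#'   compartment needs a path to irreversible loss, equivalently all
#'   eigenvalues of `A` have strictly negative real part. Construction
#'   fails on negative or non-finite coefficients, invalid roles, or a
#'   closed (singular) system.
#'
#' @seealso [solve_tracer()], [steady_state_masses()], [build_system()]
#' @export
#' @examples
#' sys <- compartmental_system(matrix(0, 1, 1), loss = 0.1)
#' sys$n
compartmental_system <- function(transfer, loss, dosing = 1L,
                                 plasma = NULL, storage = NULL,
                                 delay = NULL, absorption_fraction = 1) {
  transfer <- as.matrix(transfer)
  n <- nrow(transfer)
  if (ncol(transfer) != n) {
    stop("`transfer` must be a square matrix", call. = FALSE)
  }
  if (length(loss) == 1L && n > 1L) loss <- rep(loss, n)
  if (length(loss) != n) {
    stop("`loss` must have one coefficient per compartment", call. = FALSE)
  }
  if (!all(is.finite(transfer)) || !all(is.finite(loss))) {
    stop("transfer and loss coefficients must be finite", call. = FALSE)
  }
  if (any(transfer < 0) || any(loss < 0)) {
    bad <- which(transfer < 0, arr.ind = TRUE)
    lab <- if (nrow(bad) > 0) {
      sprintf("L(%d,%d)", bad[1, 1], bad[1, 2])
    } else {
      sprintf("L(0,%d)", which(loss < 0)[1])
    }
    stop("negative coefficient: ", lab, call. = FALSE)
  }
  if (any(diag(transfer) != 0)) {
    stop("diagonal of `transfer` must be zero (L(j,j) is implied)",
         call. = FALSE)
  }

  check_index <- function(i, what) {
    if (length(i) != 1L || !is.finite(i) || i < 1 || i > n || i != round(i)) {
      stop(sprintf("invalid %s compartment index", what), call. = FALSE)
    }
    as.integer(i)
  }
  dosing <- check_index(dosing, "dosing")
  if (!is.null(plasma)) plasma <- check_index(plasma, "plasma")
  if (!is.null(storage)) {
    if (length(storage) != 2L) {
      stop("`storage` must name exactly 2 compartments", call. = FALSE)
    }
    storage <- sort(c(check_index(storage[1], "storage"),
                      check_index(storage[2], "storage")))
    if (storage[1] == storage[2]) {
      stop("`storage` must name exactly 2 distinct compartments",
           call. = FALSE)
    }
    if (!is.null(plasma) && plasma %in% storage) {
      stop("plasma compartment cannot be a storage compartment",
           call. = FALSE)
    }
    if (dosing %in% storage) {
      stop("dosing compartment cannot be a storage compartment",
           call. = FALSE)
    }
  }

  if (!is.null(delay)) {
    if (!is.list(delay) || is.null(delay$duration)) {
      stop("`delay` must be list(duration = , stages = )", call. = FALSE)
    }
    if (is.null(delay$stages)) delay$stages <- 3L
    if (delay$duration <= 0 || delay$stages < 1 ||
        delay$stages != round(delay$stages)) {
      stop("delay duration must be > 0 and stages a positive integer",
           call. = FALSE)
    }
    delay$stages <- as.integer(delay$stages)
  }

  if (!is.finite(absorption_fraction) || absorption_fraction <= 0 ||
      absorption_fraction > 1) {
    stop("`absorption_fraction` must lie in (0, 1]", call. = FALSE)
  }

  sys <- structure(
    list(n = n, transfer = transfer, loss = as.numeric(loss),
         dosing = dosing, plasma = plasma, storage = storage,
         delay = delay, absorption_fraction = absorption_fraction),
    class = "compartmental_system"
  )

  # openness: all eigenvalues of the state matrix strictly in the left
  # half-plane, otherwise some material can never reach irreversible loss
  ev <- eigen(state_matrix(sys), only.values = TRUE)$values
  if (max(Re(ev)) > -1e-12) {
    stop("unreachable loss: system is closed (state matrix is singular ",
         "or has a nonnegative eigenvalue)", call. = FALSE)
  }
  sys
}

#' State matrix of a compartmental system
#'
#' Returns the `n x n` matrix `A` governing `dq/dt = A q` for the declared
#' compartments (the absorptive delay chain is handled separately by the
#' solver).
#'
#' @param system a `compartmental_system`.
#' @return numeric matrix.
#' @export
state_matrix <- function(system) {
  stopifnot(inherits(system, "compartmental_system"))
  A <- system$transfer
  diag(A) <- -(colSums(system$transfer) + system$loss)
  A
}

#' @export
print.compartmental_system <- function(x, ...) {
  cat(sprintf("<compartmental_system: %d compartments>\n", x$n))
  cat(sprintf("  dosing: %d", x$dosing))
  if (!is.null(x$plasma)) cat(sprintf("  plasma: %d", x$plasma))
  if (!is.null(x$storage)) {
    cat(sprintf("  storage: {%s}", paste(x$storage, collapse = ", ")))
  }
  cat("\n")
  if (!is.null(x$delay)) {
    cat(sprintf("  delay: %.3g d in %d stages\n",
                x$delay$duration, x$delay$stages))
  }
  cat(sprintf("  absorption fraction: %.3g\n", x$absorption_fraction))
  nz <- sum(x$transfer > 0) + sum(x$loss > 0)
  cat(sprintf("  %d nonzero rate coefficients\n", nz))
  invisible(x)
}

#' Build a compartmental system from a labeled coefficient table
#'
#' Assembles a validated [compartmental_system()] from one row of a subject
#' parameter table. Transfer coefficients are read from columns named
#' `L_i_j` (value of `L(i,j)` in 1/day, with `i = 0` denoting irreversible
#' loss); delay and absorption settings come from `delay_duration`,
#' `delay_stages` and `absorption_fraction` columns when present.
#' Compartment roles come from `topology`. A declared coefficient that is
#' missing (`NA`) is an error: construction never silently defaults a
#' value.
#'
#' @param params a one-row data frame or named list/vector with `L_i_j`
#'   entries and optional `delay_duration`, `delay_stages`,
#'   `absorption_fraction`.
#' @param topology list with elements `dosing`, `plasma`, `storage`
#'   (and optionally `n_compartments`); defaults to [default_topology()].
#' @return a `compartmental_system`.
#' @export
#' @examples
#' build_system(list(L_0_1 = 0.1), topology = list(dosing = 1))
build_system <- function(params, topology = default_topology()) {
  if (is.data.frame(params)) {
    if (nrow(params) != 1L) {
      stop("`params` must be a single row", call. = FALSE)
    }
    params <- as.list(params)
  }
  params <- as.list(params)
  nm <- names(params)
  lcols <- grep("^L_[0-9]+_[0-9]+$", nm, value = TRUE)
  if (length(lcols) == 0L) {
    stop("no L_i_j coefficient columns found", call. = FALSE)
  }
  idx <- do.call(rbind, lapply(strsplit(sub("^L_", "", lcols), "_"),
                               as.integer))
  n <- topology$n_compartments %||% max(idx)
  transfer <- matrix(0, n, n)
  loss <- numeric(n)
  for (k in seq_along(lcols)) {
    v <- params[[lcols[k]]]
    if (is.null(v) || is.na(v) || !is.numeric(v)) {
      stop("missing or non-numeric coefficient ", lcols[k], call. = FALSE)
    }
    i <- idx[k, 1]; j <- idx[k, 2]
    if (j < 1 || j > n || i > n) {
      stop("coefficient index out of range: ", lcols[k], call. = FALSE)
    }
    if (i == 0) loss[j] <- v else transfer[i, j] <- v
  }

  delay <- NULL
  dd <- params$delay_duration
  if (!is.null(dd) && !is.na(dd) && dd > 0) {
    ds <- params$delay_stages
    delay <- list(duration = dd,
                  stages = if (is.null(ds) || is.na(ds)) 3L else ds)
  }
  af <- params$absorption_fraction
  if (is.null(af) || is.na(af)) af <- 1

  compartmental_system(
    transfer, loss,
    dosing = topology$dosing %||% 1L,
    plasma = topology$plasma,
    storage = topology$storage,
    delay = delay,
    absorption_fraction = af
  )
}

#' Default compartment roles
#'
#' The package's default eight-compartment arrangement for whole-body
#' vitamin A kinetics after an oral dose of labeled retinyl acetate:
#' the dose enters the gut (1), is absorbed via chylomicrons (2) and
#' hepatic processing (3), reaches plasma retinol (5) which exchanges with
#' a fast-turnover tissue pool (4) and with two slowly turning-over
#' storage pools (6, hepatic; 7, extrahepatic); irreversible utilization
#' occurs from a post-plasma catabolic pool (8).
#'
#' @return list with `n_compartments`, `dosing`, `plasma`, `storage`.
#' @export
default_topology <- function() {
  list(n_compartments = 8L, dosing = 1L, plasma = 5L, storage = c(6L, 7L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
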