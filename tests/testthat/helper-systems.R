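# Fixtures built in code: small analytic systems, random open systems,
# and a deterministic 8-compartment subject.

one_comp <- function(k = 0.1) {
  compartmental_system(matrix(0, 1, 1), loss = k)
}

# intake -> 1 -> 2 -> loss; analytic tracer solution available
two_comp_chain <- function(k12 = 0.5, k02 = 0.25) {
  tr <- matrix(0, 2, 2)
  tr[2, 1] <- k12
  compartmental_system(tr, loss = c(0, k02))
}

# random sparse open system; guaranteed valid by construction + retry
random_open_system <- function(n = 4) {
  repeat {
    tr <- matrix(stats::runif(n * n, 0, 2), n, n)
    tr[stats::runif(n * n) < 0.4] <- 0
    diag(tr) <- 0
    loss <- stats::runif(n, 0.05, 1)
    sys <- tryCatch(compartmental_system(tr, loss),
                    error = function(e) NULL)
    if (!is.null(sys)) return(sys)
  }
}

# one fixed adult-like subject (no RNG)
fixed_subject <- function(M5 = 6, absorption = 0.75, delay = TRUE) {
  tr <- matrix(0, 8, 8)
  tr[2, 1] <- 60
  tr[3, 2] <- 120
  tr[5, 3] <- 1.3; tr[6, 3] <- 5
  tr[4, 5] <- 9;   tr[5, 4] <- 18
  tr[6, 5] <- 0.6; tr[5, 6] <- 0.012
  tr[7, 5] <- 0.25; tr[5, 7] <- 0.007
  tr[8, 5] <- 0.4
  loss <- c(0, 0, 0, 0, 0, 0, 0, 1)
  sys <- compartmental_system(
    tr, loss, dosing = 1, plasma = 5, storage = c(6, 7),
    delay = if (delay) list(duration = 0.25, stages = 3L) else NULL,
    absorption_fraction = absorption)
  subject_spec("fix_01", "adult", sys, M5)
}

# subjects sharing one system but with different plasma pool sizes: their
# FaS curves coincide exactly, so group-coefficient predictions are exact
m5_family <- function(M5s = c(3, 5, 8)) {
  lapply(seq_along(M5s), function(i) {
    s <- fixed_subject(M5 = M5s[i])
    s$id <- sprintf("fam_%02d", i)
    s
  })
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.eps)), tol)
}
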