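#' Read a subject parameter table
#'
#' Loads a CSV of per-subject kinetic parameters and plasma pool sizes
#' and returns validated subjects with assigned TBS computed. The schema
#' has one row per subject with columns `subject_id`, `group`, the
#' fractional transfer coefficients as `L_i_j` columns (1/day, `i = 0`
#' for irreversible loss), `delay_duration`, `delay_stages`,
#' `absorption_fraction`, and `M5_umol`.
#'
#' @param path CSV file path.
#' @param topology compartment roles: a list as from [default_topology()]
#'   or the path of a topology JSON file (see [read_topology()]).
#' @return list of [subject_spec()] objects.
#' @export
read_parameter_table <- function(path, topology = default_topology()) {
  if (is.character(topology)) topology <- read_topology(topology)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "M5_umol")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!length(grep("^L_[0-9]+_[0-9]+$", names(tab)))) {
    stop("parameter table has no L_i_j coefficient columns",
         call. = FALSE)
  }
  subjects <- lapply(seq_len(nrow(tab)), function(r) {
    row <- tab[r, , drop = FALSE]
    id <- row$subject_id
    tryCatch({
      if (!is.numeric(row$M5_umol) || is.na(row$M5_umol)) {
        stop("non-numeric M5_umol")
      }
      sys <- build_system(row, topology = topology)
      subject_spec(id, row$group, sys, row$M5_umol)
    }, error = function(e) {
      stop(sprintf("subject %s (row %d): %s", id, r,
                   conditionMessage(e)), call. = FALSE)
    })
  })
  message(sprintf("read %d subjects (%s) from %s", length(subjects),
                  paste(unique(tab$group), collapse = "/"),
                  basename(path)))
  subjects
}

#' Write a cohort to the subject parameter schema
#'
#' Serializes subjects to the same CSV schema [read_parameter_table()]
#' consumes, with full double precision so a round trip reproduces every
#' assigned TBS bit-for-bit. When the cohort carries a generation design
#' (see [generate_cohort()]) a JSON sidecar `<path>.json` records the
#' design, seed and package version.
#'
#' @param subjects list of [subject_spec()] objects.
#' @param path output CSV path.
#' @param sidecar write the provenance sidecar when a design is attached.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(subjects, path, sidecar = TRUE) {
  stopifnot(length(subjects) >= 1)
  rows <- lapply(subjects, function(s) {
    sys <- s$system
    nz <- which(sys$transfer > 0, arr.ind = TRUE)
    vals <- c(
      stats::setNames(sys$transfer[nz],
                      sprintf("L_%d_%d", nz[, 1], nz[, 2])),
      stats::setNames(sys$loss[sys$loss > 0],
                      sprintf("L_0_%d", which(sys$loss > 0)))
    )
    c(list(subject_id = s$id, group = s$group), as.list(vals),
      list(delay_duration = if (is.null(sys$delay)) 0 else sys$delay$duration,
           delay_stages = if (is.null(sys$delay)) 0L else sys$delay$stages,
           absorption_fraction = sys$absorption_fraction,
           M5_umol = s$M5))
  })
  lcols <- sort(unique(unlist(lapply(rows, function(r) {
    grep("^L_", names(r), value = TRUE)
  }))))
  cols <- c("subject_id", "group", lcols,
            "delay_duration", "delay_stages", "absorption_fraction",
            "M5_umol")
  lines <- vapply(rows, function(r) {
    paste(vapply(cols, function(cn) {
      v <- r[[cn]]
      if (is.null(v)) "0"
      else if (is.character(v)) v
      else sprintf("%.17g", v)
    }, character(1)), collapse = ",")
  }, character(1))
  writeLines(c(paste(cols, collapse = ","), lines), path)

  design <- attr(subjects, "design")
  if (sidecar && !is.null(design)) {
    meta <- list(
      design = unclass(design),
      package = "ridsim",
      version = as.character(utils::packageVersion("ridsim"))
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read and write compartment-role topology files
#'
#' Topology JSON lists the compartment roles of a parameter table:
#' `n_compartments`, `dosing`, `plasma`, and the two `storage` indices.
#'
#' @param path JSON file path.
#' @return `read_topology()` returns the roles list; `write_topology()`
#'   returns `path` invisibly.
#' @export
read_topology <- function(path) {
  topo <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("dosing", "plasma", "storage")) {
    if (!is.null(topo[[f]])) topo[[f]] <- as.integer(topo[[f]])
  }
  topo
}

#' @rdname read_topology
#' @param topology roles list.
#' @export
write_topology <- function(topology, path) {
  jsonlite::write_json(topology, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
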