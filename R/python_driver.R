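# Interface to the bundled msprime driver (inst/python/cohort_sim.py).

driver_script <- function() {
  p <- system.file("python", "cohort_sim.py", package = "stratsim")
  if (!nzchar(p)) stop("bundled python driver not found; is stratsim installed?")
  p
}

python_binary <- function() {
  p <- Sys.getenv("STRATSIM_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no 'python' interpreter on PATH (needs msprime + pyarrow)")
  p
}

run_driver <- function(args) {
  out <- suppressWarnings(system2(python_binary(), c(driver_script(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("simulation driver failed (exit ", status, "):\n",
         paste(utils::tail(out, 15), collapse = "\n"))
  }
  invisible(out)
}

read_feather_matrix <- function(path, prefix) {
  tab <- arrow::read_feather(path)
  cols <- grep(paste0("^", prefix, "[0-9]+$"), names(tab), value = TRUE)
  info <- as.data.frame(tab[setdiff(names(tab), cols)])
  # fill column-wise to avoid duplicating the whole matrix during coercion
  m <- matrix(0L, nrow(tab), length(cols))
  for (j in seq_along(cols)) m[, j] <- as.integer(tab[[cols[j]]])
  rm(tab)
  list(info = info, matrix = m)
}
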