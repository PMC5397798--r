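# Linear-program backend.
#
# The distance-learning LP is sparse and can be large (tens of thousands of
# rows); it is solved through scipy's HiGHS interface via a small bundled
# Python script. The LP is exchanged through a temporary directory holding a
# JSON header plus raw little-endian binary arrays (triplet-form constraint
# matrix, bounds, objective), and the solution comes back the same way.

.pythonBin <- function() {
  p <- Sys.getenv("COREMSA_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("no 'python' interpreter found on PATH (needed to solve the LP); ",
         "set COREMSA_PYTHON to point at one with numpy and scipy")
  p
}

# Solve min c'x  s.t.  A x <= b, x >= 0  (A in triplet form).
# Returns list(x, objective, status, message).
.solveLP <- function(i, j, v, b, obj, nRows, nCols) {
  dir <- tempfile("corelp")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  jsonlite::write_json(list(n_rows = nRows, n_cols = nCols,
                            nnz = length(v)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  wb <- function(x, name, what) {
    con <- file(file.path(dir, name), "wb")
    on.exit(close(con))
    writeBin(x, con, size = if (what == "int") 4L else 8L,
             endian = "little")
  }
  wb(as.integer(i - 1L), "ai.bin", "int")
  wb(as.integer(j - 1L), "aj.bin", "int")
  wb(as.double(v), "av.bin", "dbl")
  wb(as.double(b), "b.bin", "dbl")
  wb(as.double(obj), "c.bin", "dbl")
  script <- system.file("python", "solve_lp.py", package = "coreMSA",
                        mustWork = TRUE)
  out <- suppressWarnings(system2(.pythonBin(), c(shQuote(script), shQuote(dir)),
                                  stdout = TRUE, stderr = TRUE))
  code <- attr(out, "status")
  resFile <- file.path(dir, "result.json")
  if ((!is.null(code) && code != 0L) || !file.exists(resFile))
    stop("LP solver failed:\n", paste(out, collapse = "\n"))
  res <- jsonlite::read_json(resFile, simplifyVector = TRUE)
  if (res$status != 0L)
    stop("LP not solved to optimality (scipy status ", res$status, "): ",
         res$message)
  con <- file(file.path(dir, "x.bin"), "rb")
  x <- readBin(con, "double", n = nCols, size = 8L, endian = "little")
  close(con)
  list(x = x, objective = res$fun, status = "optimal",
       message = res$message)
}
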