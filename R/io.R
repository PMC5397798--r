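#' Build an alignment from character rows
#'
#' @param rows character vector of equal-length aligned strings
#' @param ids sequence identifiers (defaults to names of \code{rows})
#' @param ambiguous allow ambiguity codes B, Z, X, U, O
#' @return a \linkS4class{ProteinAlignment}
#' @export
proteinAlignment <- function(rows, ids = names(rows), ambiguous = FALSE) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    stop("unequal row lengths (record '", ids[which(lens != lens[1])[1]], "')")
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  m[m == "."] <- .GAP
  rownames(m) <- ids
  new("ProteinAlignment", seqs = m, ambiguous = ambiguous)
}

#' Read an aligned FASTA file
#'
#' Lowercase residues are upcased and '.' is treated as the gap character.
#' Non-standard residues are rejected unless \code{mapAmbiguous = TRUE}, in
#' which case B, Z, X, U, O are kept and expanded to uniform residue
#' distributions when profiles are built.
#'
#' @param path aligned FASTA file ('-' gaps)
#' @param mapAmbiguous permit ambiguity codes
#' @return a \linkS4class{ProteinAlignment}
#' @export
readAlignment <- function(path, mapAmbiguous = FALSE) {
  s <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("cannot parse FASTA '", path, "': ",
                                         conditionMessage(e)))
  if (length(s) == 0L) stop("empty alignment file: ", path)
  ids <- sub("\\s.*$", "", names(s))
  proteinAlignment(as.character(s), ids, ambiguous = mapAmbiguous)
}

#' Write an alignment as aligned FASTA
#' @param x a ProteinAlignment
#' @param path output file
#' @export
writeAlignment <- function(x, path) {
  rows <- apply(x@seqs, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(rows)
  names(ss) <- rownames(x@seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname proteinAlignment
#' @param x a ProteinAlignment
#' @export
nSequences <- function(x) nrow(x@seqs)

#' @rdname proteinAlignment
#' @export
nColumns <- function(x) ncol(x@seqs)

#' @rdname proteinAlignment
#' @export
msaIDs <- function(x) rownames(x@seqs)

#' @rdname proteinAlignment
#' @export
msaMatrix <- function(x) x@seqs

#' Ungapped sequences of an alignment
#' @param x a ProteinAlignment
#' @return named character vector of degapped sequences
#' @export
ungappedSeqs <- function(x) {
  apply(x@seqs, 1L, function(r) paste(r[r != .GAP], collapse = ""))
}

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns\n",
              nrow(object@seqs), ncol(object@seqs)))
  ids <- rownames(object@seqs)
  shown <- utils::head(ids, 3L)
  cat("  ids: ", paste(shown, collapse = ", "),
      if (length(ids) > 3L) ", ..." else "", "\n", sep = "")
})

## ---- secondary structure (.ss2) ------------------------------------------

#' Read a PSIPRED .ss2 confidence file for one sequence
#'
#' Data rows follow PSIPRED VFORMAT: index, residue, state letter, then the
#' coil, helix and strand confidences. Internally columns are reordered to
#' (H, E, C) = (helix, strand, coil) and renormalized to sum to 1.
#'
#' @param path .ss2 file
#' @return numeric matrix (residues x 3), columns H, E, C; attribute
#'   \code{residues} carries the residue letters
#' @export
readSS2 <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[[:space:]]+")
  keep <- vapply(fields, length, 1L) >= 6L
  fields <- fields[keep]
  if (!length(fields)) stop("no data rows in ss2 file: ", path)
  conf <- t(vapply(fields, function(f) as.numeric(f[4:6]), numeric(3)))
  if (anyNA(conf)) stop("malformed confidence values in ", path)
  if (min(conf) < 0) stop("negative confidence value in ", path)
  res <- vapply(fields, `[`, "", 2L)
  # VFORMAT order is (coil, helix, strand) -> internal (helix, strand, coil)
  conf <- conf[, c(2L, 3L, 1L), drop = FALSE]
  tot <- rowSums(conf)
  if (any(tot <= 0)) stop("all-zero confidence row in ", path)
  conf <- conf / tot
  colnames(conf) <- .SS3
  attr(conf, "residues") <- toupper(res)
  conf
}

#' Write a PSIPRED-style .ss2 confidence file
#' @param conf residues x 3 matrix with columns H, E, C
#' @param residues residue letters (defaults to the matrix attribute)
#' @param path output file
#' @export
writeSS2 <- function(conf, path, residues = attr(conf, "residues")) {
  if (is.null(residues)) residues <- rep("A", nrow(conf))
  state <- .SS3[max.col(conf, ties.method = "first")]
  # back to VFORMAT column order (coil, helix, strand)
  lines <- sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                   seq_len(nrow(conf)), residues, state,
                   conf[, "C"], conf[, "H"], conf[, "E"])
  writeLines(c("# PSF format file", "", lines), path)
  invisible(path)
}

#' Check secondary-structure tracks against an alignment
#'
#' @param alignment a ProteinAlignment
#' @param ss named list of confidence matrices (one per sequence, rows =
#'   non-gap residues)
#' @return invisibly TRUE; errors on any mismatch
#' @export
validateSS <- function(alignment, ss) {
  ids <- msaIDs(alignment)
  if (!all(ids %in% names(ss)))
    stop("missing secondary structure for: ",
         paste(setdiff(ids, names(ss)), collapse = ", "))
  nres <- rowSums(alignment@seqs != .GAP)
  for (id in ids) {
    if (nrow(ss[[id]]) != nres[[id]])
      stop("length mismatch for '", id, "': ", nrow(ss[[id]]),
           " ss2 rows vs ", nres[[id]], " residues")
  }
  invisible(TRUE)
}

## ---- core-column annotation ----------------------------------------------

#' Read a core-column annotation TSV
#'
#' Format: header \code{column<TAB>coreness}, then 1-based column indices
#' with coreness weights in [0,1]. Unlisted columns default to 0.
#'
#' @param path TSV file
#' @param nColumns number of columns in the annotated alignment
#' @return numeric vector of length \code{nColumns}
#' @export
readCoreAnnotation <- function(path, nColumns) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric"))
  out <- numeric(nColumns)
  if (nrow(df)) {
    if (any(df$column < 1L | df$column > nColumns))
      stop("column index out of range 1..", nColumns)
    if (any(df$coreness < 0 | df$coreness > 1))
      stop("coreness outside [0,1]")
    out[df$column] <- df$coreness
  }
  out
}

#' @rdname readCoreAnnotation
#' @param coreness numeric vector of per-column coreness weights
#' @export
writeCoreAnnotation <- function(coreness, path) {
  keep <- which(coreness != 0)
  df <- data.frame(column = keep, coreness = coreness[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- benchmark manifests -------------------------------------------------

#' Write a benchmark manifest
#'
#' JSON with keys \code{reference}, \code{core_annotation}, \code{ss2}
#' (named list id -> path), and \code{computed}: a list of
#' \code{{id, path, accuracy}} entries (accuracy optional: the realized true
#' accuracy recorded by the generator).
#'
#' @param manifest a list with those keys
#' @param path output JSON path
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("reference", "core_annotation", "ss2", "computed")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing key(s): ", paste(miss, collapse = ", "))
  m
}

#' Load a benchmark from its manifest
#'
#' Reads the reference alignment, core annotation, per-sequence secondary
#' structure, and all computed alignments; paths in the manifest are
#' resolved relative to the manifest's directory.
#'
#' @param path manifest JSON path
#' @return list with elements \code{reference}, \code{annotation}, \code{ss},
#'   \code{computed} (named list of ProteinAlignment), \code{accuracy}
#'   (recorded accuracies, NA where absent)
#' @export
loadBenchmark <- function(path) {
  m <- readManifest(path)
  dir <- dirname(path)
  rel <- function(p) if (startsWith(p, "/")) p else file.path(dir, p)
  ref <- readAlignment(rel(m$reference))
  ann <- readCoreAnnotation(rel(m$core_annotation), nColumns(ref))
  ss <- lapply(m$ss2, function(p) readSS2(rel(p)))
  ids <- vapply(m$computed, function(x) x$id, "")
  if (anyDuplicated(ids)) stop("duplicate parameter ids in manifest")
  comp <- lapply(m$computed, function(x) readAlignment(rel(x$path)))
  names(comp) <- ids
  acc <- vapply(m$computed,
                function(x) if (is.null(x$accuracy)) NA_real_ else x$accuracy,
                numeric(1))
  names(acc) <- ids
  validateSS(ref, ss)
  list(reference = ref, annotation = ann, ss = ss,
       computed = comp, accuracy = acc)
}

## ---- model serialization -------------------------------------------------

.MODEL_SCHEMA <- "coreMSA-model"
.MODEL_VERSION <- 1L

.alphabetToList <- function(a) list(name = a@name, groups = as.list(a@groups))

.alphabetFromList <- function(l) {
  g <- unlist(l$groups)
  if (l$name %in% c("full", "reduced5", "reduced3")) stateAlphabet(l$name)
  else stateAlphabet("custom", groups = g)
}

.transformToList <- function(t) {
  list(kappa = t@kappa, lambda = t@lambda, slope = t@slope,
       inflection = t@inflection, degenerate = t@degenerate)
}

.transformFromList <- function(l) {
  for (f in c("kappa", "lambda", "slope", "inflection"))
    if (is.null(l[[f]])) stop("model file schema error: transform lacks '", f, "'")
  new("LogisticTransform", kappa = l$kappa, lambda = l$lambda,
      slope = l$slope, inflection = l$inflection,
      degenerate = isTRUE(l$degenerate))
}

#' Save or load a model as JSON
#'
#' Handles \linkS4class{DistanceModel}, \linkS4class{CorenessRegressor},
#' \linkS4class{NormalizerModel} and \linkS4class{EstimatorModel}. Floats are
#' written at full precision so that \code{loadModel(saveModel(x))} matches
#' \code{x} field by field. Files carry a schema-version field; unknown
#' versions are rejected.
#'
#' @param model the model object
#' @param path JSON file path
#' @export
saveModel <- function(model, path) {
  body <- if (is(model, "DistanceModel")) {
    list(type = "DistanceModel", width = model@width, tau = model@tau,
         alphabet = .alphabetToList(model@alphabet),
         sigma = lapply(model@sigma, function(a) {
           lapply(seq_len(dim(a)[3]), function(i) a[, , i])
         }))
  } else if (is(model, "CorenessRegressor")) {
    list(type = "CorenessRegressor",
         model = jsonlite::fromJSON(saveModelJSON(model@model),
                                    simplifyVector = FALSE),
         train = lapply(model@train, identity),
         f_core = .transformToList(model@fCore),
         f_non = .transformToList(model@fNon))
  } else if (is(model, "NormalizerModel")) {
    list(type = "NormalizerModel",
         coefficients = as.list(model@coefficients))
  } else if (is(model, "EstimatorModel")) {
    list(type = "EstimatorModel",
         coefficients = as.list(model@coefficients))
  } else stop("unsupported model class: ", class(model))
  out <- c(list(schema = .MODEL_SCHEMA, version = .MODEL_VERSION), body)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# JSON text of a model (used to nest a DistanceModel inside a regressor file)
saveModelJSON <- function(model) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  saveModel(model, tf)
  paste(readLines(tf, warn = FALSE), collapse = "\n")
}

.distanceModelFromList <- function(m) {
  for (f in c("width", "tau", "alphabet", "sigma"))
    if (is.null(m[[f]])) stop("model file schema error: missing '", f, "'")
  alpha <- .alphabetFromList(m$alphabet)
  ns <- nStates(alpha)
  P <- 2L * as.integer(m$width) + 1L
  sigma <- lapply(m$sigma, function(tabs) {
    a <- array(0, dim = c(ns, ns, P))
    for (i in seq_len(P))
      a[, , i] <- matrix(unlist(tabs[[i]]), ns, ns)
    a
  })
  new("DistanceModel", sigma = sigma[.STRUCTURED_CLASSES],
      tau = m$tau, width = as.integer(m$width), alphabet = alpha)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(m$schema, .MODEL_SCHEMA))
    stop("not a coreMSA model file: ", path)
  if (!identical(as.integer(m$version), .MODEL_VERSION))
    stop("unsupported model schema version: ", m$version)
  switch(m$type,
    DistanceModel = .distanceModelFromList(m),
    CorenessRegressor = {
      dm <- .distanceModelFromList(m$model)
      train <- lapply(m$train, function(rows) {
        do.call(rbind, lapply(rows, unlist))
      })
      reg <- new("CorenessRegressor", model = dm,
                 train = train[.STRUCTURED_CLASSES],
                 indices = list(),
                 fCore = .transformFromList(m$f_core),
                 fNon = .transformFromList(m$f_non))
      rebuildIndices(reg)
    },
    NormalizerModel = new("NormalizerModel",
                          coefficients = unlist(m$coefficients)),
    EstimatorModel = new("EstimatorModel",
                         coefficients = unlist(m$coefficients)),
    stop("unknown model type: ", m$type))
}
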