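#' @import methods
NULL

# Window-class vocabulary (width w = 1 patterns; see windowClass() for how
# wider windows are reduced to these).
.ALL_CLASSES <- c("CCC", "CCN", "NCC", "CNN", "NNC", "NNN")
.STRUCTURED_CLASSES <- c("CCC", "CCN", "NCC", "CNN", "NNC")
.CORE_CLASSES <- c("CCC", "CCN", "NCC")
.EXCLUDED_PATTERNS <- c("NCN", "CNC")

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.SS3 <- c("H", "E", "C")   # alpha-helix, beta-strand, coil
.GAP <- "-"

#' State alphabet for column profiles
#'
#' Joint (residue group, secondary structure) states plus the gap state.
#' The full alphabet has 20 x 3 + 1 = 61 states; reduced alphabets replace
#' the 20 amino acids by equivalence-class symbols.
#'
#' @slot name alphabet identifier ("full", "reduced5", ...)
#' @slot groups named character vector mapping each of the 20 amino acids to
#'   its residue symbol in this alphabet
#' @slot residues the distinct residue symbols
#' @slot states state names, residue-major then secondary structure
#'   (H, E, C), with the gap state "--" last
#' @exportClass StateAlphabet
setClass("StateAlphabet",
  representation(name = "character", groups = "character",
                 residues = "character", states = "character"))

setValidity("StateAlphabet", function(object) {
  if (!setequal(names(object@groups), .AA20))
    return("groups must map exactly the 20 standard amino acids")
  if (!setequal(unique(unname(object@groups)), object@residues))
    return("residues must be the distinct group symbols")
  n <- length(object@residues)
  if (length(object@states) != 3L * n + 1L)
    return("states must have 3 * residues + 1 entries")
  if (object@states[length(object@states)] != "--")
    return("last state must be the gap state '--'")
  TRUE
})

#' An aligned set of protein sequences
#'
#' Rows are equal-length strings over the 20 amino acids plus the gap
#' character '-'. Stored as a character matrix with one row per sequence.
#'
#' @slot seqs character matrix (k sequences x m columns) with rownames the
#'   sequence identifiers
#' @slot ambiguous whether ambiguity codes (B, Z, X, U, O) are permitted;
#'   when TRUE they are expanded to uniform residue distributions at
#'   profile-construction time
#' @exportClass ProteinAlignment
setClass("ProteinAlignment",
  representation(seqs = "matrix", ambiguous = "logical"),
  prototype(ambiguous = FALSE))

.AMBIG <- list(B = c("D", "N"), Z = c("E", "Q"), X = .AA20,
               U = "C", O = "K")

setValidity("ProteinAlignment", function(object) {
  if (!is.character(object@seqs)) return("seqs must be a character matrix")
  if (nrow(object@seqs) < 2L) return("an alignment needs at least 2 sequences")
  if (is.null(rownames(object@seqs))) return("seqs must carry rownames (ids)")
  if (anyDuplicated(rownames(object@seqs))) return("duplicate sequence ids")
  ok <- c(.AA20, .GAP, if (object@ambiguous) names(.AMBIG))
  bad <- setdiff(unique(as.vector(object@seqs)), ok)
  if (length(bad))
    return(paste0("illegal symbol(s): ", paste(bad, collapse = ", ")))
  TRUE
})

#' A set of column windows as flattened profile vectors
#'
#' Each row holds the 2w+1 column profiles of one window, concatenated
#' position-major (position -w first), each profile a distribution over the
#' alphabet's states. Metadata about each window (source benchmark, column
#' index, core/non-core label, window class, true coreness) lives in
#' \code{info}.
#'
#' @slot profiles numeric matrix, one window per row, (2w+1) * nStates columns
#' @slot width window half-width w
#' @slot alphabet the StateAlphabet the profiles are expressed in
#' @slot info data.frame with one row per window
#' @exportClass WindowSet
setClass("WindowSet",
  representation(profiles = "matrix", width = "integer",
                 alphabet = "StateAlphabet", info = "data.frame"))

setValidity("WindowSet", function(object) {
  P <- 2L * object@width + 1L
  ns <- length(object@alphabet@states)
  if (ncol(object@profiles) != P * ns)
    return("profile matrix width must equal (2w+1) * nStates")
  if (nrow(object@info) != nrow(object@profiles))
    return("info must have one row per window")
  # per-position sums checked cheaply: total mass must be 2w+1 per window
  tot <- rowSums(object@profiles)
  if (nrow(object@profiles) && any(abs(tot - P) > 1e-6 * P))
    return("each of the 2w+1 profiles must sum to 1")
  TRUE
})

#' Learned class-specific window distance functions
#'
#' Per structured class and window position, a symmetric non-negative
#' substitution-score table over states, plus the learned distance
#' threshold tau.
#'
#' @slot sigma named list (one per structured class) of 3D arrays
#'   nStates x nStates x (2w+1)
#' @slot tau non-negative distance threshold
#' @slot width window half-width
#' @slot alphabet StateAlphabet
#' @exportClass DistanceModel
setClass("DistanceModel",
  representation(sigma = "list", tau = "numeric", width = "integer",
                 alphabet = "StateAlphabet"))

setValidity("DistanceModel", function(object) {
  if (!setequal(names(object@sigma), .STRUCTURED_CLASSES))
    return("sigma must have one table set per structured class")
  ns <- length(object@alphabet@states)
  P <- 2L * object@width + 1L
  for (cl in names(object@sigma)) {
    a <- object@sigma[[cl]]
    if (!is.array(a) || !all(dim(a) == c(ns, ns, P)))
      return(sprintf("sigma[[%s]] must be %d x %d x %d", cl, ns, ns, P))
    if (min(a) < -1e-9) return("substitution scores must be non-negative")
    for (i in seq_len(P)) {
      if (max(abs(a[, , i] - t(a[, , i]))) > 1e-9)
        return("substitution scores must be symmetric")
      if (abs(a[ns, ns, i]) > 1e-9)
        return("sigma(gap, gap) must be 0")
    }
  }
  if (length(object@tau) != 1L || object@tau < -1e-9)
    return("tau must be a single non-negative number")
  TRUE
})

#' Exact metric nearest-neighbor index (vantage-point tree)
#'
#' @slot data flattened window profiles (one row per indexed window)
#' @slot tree nested-list vp-tree over row indices
#' @slot model DistanceModel used for all distances
#' @slot class structured class whose distance function applies
#' @slot brute fall back to linear scan (set when the model failed
#'   triangle verification)
#' @exportClass NNIndex
setClass("NNIndex",
  representation(data = "matrix", tree = "list", model = "DistanceModel",
                 wclass = "character", brute = "logical"))

#' Four-parameter logistic transform from distance to coreness
#'
#' f(x) = kappa + (lambda - kappa) / (1 + exp(-slope * (x - inflection))).
#' kappa and lambda are the floor and ceiling (the minimum and maximum
#' average-coreness values observed while fitting); slope and inflection are
#' fitted. A degenerate fit (lambda == kappa) evaluates to the constant.
#'
#' @exportClass LogisticTransform
setClass("LogisticTransform",
  representation(kappa = "numeric", lambda = "numeric", slope = "numeric",
                 inflection = "numeric", degenerate = "logical"),
  prototype(degenerate = FALSE))

#' The coreness regressor
#'
#' Bundles the learned distance model, the per-class training windows with
#' their nearest-neighbor indices, and the two logistic transforms
#' (fCore for core nearest classes, fNon for structured non-core).
#'
#' @exportClass CorenessRegressor
setClass("CorenessRegressor",
  representation(model = "DistanceModel", train = "list", indices = "list",
                 fCore = "LogisticTransform", fNon = "LogisticTransform"))

setValidity("CorenessRegressor", function(object) {
  if (!setequal(names(object@train), .STRUCTURED_CLASSES))
    return("training windows needed for each structured class")
  TRUE
})

#' Core-column-count normalizer
#'
#' Non-negative coefficients over candidate terms, each term the product of
#' one sequence-length aggregate and at most two pairwise ratios from
#' distinct ratio groups.
#'
#' @exportClass NormalizerModel
setClass("NormalizerModel", representation(coefficients = "numeric"))

setValidity("NormalizerModel", function(object) {
  if (is.null(names(object@coefficients))) return("coefficients must be named")
  if (any(object@coefficients < -1e-9)) return("coefficients must be >= 0")
  TRUE
})

#' Alignment accuracy estimator
#'
#' Non-negative coefficients over feature functions; the estimate is the
#' dot product of coefficients and feature values.
#'
#' @exportClass EstimatorModel
setClass("EstimatorModel", representation(coefficients = "numeric"))

setValidity("EstimatorModel", function(object) {
  if (is.null(names(object@coefficients))) return("coefficients must be named")
  if (any(object@coefficients < -1e-9)) return("coefficients must be >= 0")
  if (!any(object@coefficients > 0)) return("need at least one non-zero coefficient")
  TRUE
})

#' Assembled training/testing window sets
#'
#' Index-based views into a window pool: full per-class training sets Tc,
#' training samples Sc (subsets of Tc), a subsample of the unstructured
#' class used for bottom-impostor constraints, and a held-out test set.
#'
#' @exportClass WindowSets
setClass("WindowSets",
  representation(pool = "WindowSet", Tc = "list", Sc = "list",
                 bottom = "integer", test = "integer",
                 trainPool = "integer", seed = "integer",
                 sizes = "list"),
  prototype(trainPool = integer(0)))

setValidity("WindowSets", function(object) {
  for (cl in names(object@Sc))
    if (!all(object@Sc[[cl]] %in% object@Tc[[cl]]))
      return("each Sc must be a subset of its Tc")
  TRUE
})
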