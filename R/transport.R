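#' Canonical ion-transport pathway names
#'
#' The 13 maximal-rate parameters that are randomised when heterogeneous
#' cell populations are generated, in their canonical column order:
#' fast Na+ current (`GNa`), inward-rectifier K+ current (`GK1`), rapid and
#' slow delayed-rectifier K+ currents (`GKr`, `GKs`), transient-outward K+
#' current (`Gto`), L-type Ca2+ current (`GCaL`), Na+/Ca2+ exchanger
#' (`KNCX`), Na+/K+ pump (`KNaK`), sarcolemmal Ca2+ pump (`GpCa`),
#' background Na+ and Ca2+ currents (`GbNa`, `GbCa`), SR Ca2+ release
#' (`KRyR`) and SR Ca2+ uptake (`KSERCA`).
#'
#' @return Character vector of the 13 pathway names.
#' @export
transport_pathways <- function() {
  c("GNa", "GK1", "GKr", "GKs", "Gto", "GCaL", "KNCX", "KNaK",
    "GpCa", "GbNa", "GbCa", "KRyR", "KSERCA")
}

#' Build a transport scaling vector
#'
#' A transport scaling is a named numeric vector with one positive,
#' dimensionless multiplier per ion-transport pathway.  Unspecified
#' pathways default to 1 (no change).
#'
#' @param ... Named multipliers, e.g. `GKr = 0.5`, or a single named
#'   numeric vector.
#' @return Named numeric vector over all 13 pathways, in canonical order.
#' @examples
#' transport_scaling(GKr = 0.5)
#' @export
transport_scaling <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.numeric(args[[1]])) {
    args <- as.list(args[[1]])
  }
  keys <- transport_pathways()
  out <- stats::setNames(rep(1.0, length(keys)), keys)
  if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == "")) {
      stop("all multipliers must be named with pathway keys")
    }
    bad <- setdiff(nm, keys)
    if (length(bad)) {
      stop("unknown pathway key(s): ", paste(bad, collapse = ", "),
           "; valid keys are: ", paste(keys, collapse = ", "))
    }
    out[nm] <- as.numeric(unlist(args))
  }
  validate_scaling(out)
  out
}

validate_scaling <- function(scaling) {
  keys <- transport_pathways()
  if (!is.numeric(scaling)) stop("scaling must be numeric")
  missing <- setdiff(keys, names(scaling))
  if (length(missing)) {
    stop("scaling is missing pathway key(s): ", paste(missing, collapse = ", "))
  }
  vals <- scaling[keys]
  bad <- keys[!is.finite(vals) | vals <= 0]
  if (length(bad)) {
    stop("scaling multipliers must be positive and finite; offending key(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(scaling)
}

#' Apply a transport scaling to a cell model
#'
#' Multiplies the model's 13 maximal-rate transport parameters by the
#' corresponding scaling factors.  All other parameters are untouched and
#' the input model is not modified.  Scalings compose multiplicatively:
#' applying `a` then `b` equals applying the element-wise product.
#'
#' @param model A `cell_model` object (see [fixture_model()]).
#' @param scaling Named multipliers as accepted by [transport_scaling()].
#' @return A new `cell_model` with scaled transport parameters.
#' @examples
#' m <- fixture_model("adult")
#' m50 <- apply_scaling(m, c(GKr = 0.5))
#' @export
apply_scaling <- function(model, scaling) {
  stopifnot(inherits(model, "cell_model"))
  scaling <- transport_scaling(scaling)
  keys <- transport_pathways()
  model$params[keys] <- model$params[keys] * scaling[keys]
  model
}

#' Apply a parameter-variant table to a cell model
#'
#' Variant tables describe disease or species variants as an ordered list
#' of multiplicative parameter modifications applied on top of a base
#' model (for example a heart-failure variant with reduced SERCA activity
#' and upregulated NCX).  Factors compose multiplicatively with
#' [apply_scaling()], so the order of the two operations does not matter.
#'
#' @param model A `cell_model` object.
#' @param table Data frame with columns `parameter` and `factor`, or a
#'   named numeric vector of factors.
#' @return A new `cell_model` with modified parameters.
#' @examples
#' hf <- apply_variant(fixture_model("adult"),
#'                     c(KSERCA = 0.5, KNCX = 1.75, GKs = 0.5))
#' @export
apply_variant <- function(model, table) {
  stopifnot(inherits(model, "cell_model"))
  if (is.numeric(table) && !is.null(names(table))) {
    table <- data.frame(parameter = names(table), factor = as.numeric(table),
                        stringsAsFactors = FALSE)
  }
  if (!is.data.frame(table) || !all(c("parameter", "factor") %in% names(table))) {
    stop("variant table must have columns 'parameter' and 'factor'")
  }
  if (nrow(table) == 0L) return(model)
  if (any(!is.finite(table$factor) | table$factor <= 0)) {
    stop("variant factors must be positive and finite")
  }
  bad <- setdiff(table$parameter, names(model$params))
  if (length(bad)) {
    stop("unknown model parameter(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(names(model$params), collapse = ", "))
  }
  for (i in seq_len(nrow(table))) {
    model$params[[table$parameter[i]]] <-
      model$params[[table$parameter[i]]] * table$factor[i]
  }
  model
}

#' Invert a variant table
#'
#' @param table As for [apply_variant()].
#' @return The inverse table (reciprocal factors, reverse order).
#' @export
invert_variant <- function(table) {
  if (is.numeric(table) && !is.null(names(table))) {
    table <- data.frame(parameter = names(table), factor = as.numeric(table),
                        stringsAsFactors = FALSE)
  }
  table <- table[rev(seq_len(nrow(table))), , drop = FALSE]
  table$factor <- 1 / table$factor
  rownames(table) <- NULL
  table
}
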