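#' Atom featurization specification
#'
#' Defines the ordered list of per-atom featurizers whose concatenation forms
#' a node's feature vector. Available featurizers:
#'
#' * `element` — one-hot over `element_set` plus a trailing "other" slot.
#' * `degree` — heavy-atom degree, one-hot over 0..5 (clamped at 5).
#' * `formal_charge` — signed scalar.
#' * `hybridization` — one-hot over \{sp, sp2, sp3, other\}, derived from the
#'   incident bond orders on the final polymer topology.
#' * `h_count` — implicit hydrogen count, one-hot over 0..4 (clamped),
#'   recomputed on the final topology from standard valences.
#' * `partial_charge` — scalar iterative electronegativity-equalization
#'   partial charge computed on the final topology (see
#'   [partial_charges()]).
#'
#' Featurizers that would encode membership in the macrocycle are rejected:
#' the cyclic polymer representation stands in for an infinite linear chain
#' only as long as no node can tell it sits on a ring.
#'
#' @param featurizers Ordered character vector of featurizer identifiers.
#' @param include_partial_charge Convenience toggle; when `FALSE` the
#'   `partial_charge` featurizer is dropped from the default list.
#' @param element_set Element vocabulary for the one-hot block (an "other"
#'   slot is always appended).
#' @return An object of class `atom_feature_spec` with fields `featurizers`,
#'   `element_set`, `degree_range`, `hybridization_set`, `h_range`,
#'   `include_partial_charge` and `total_dim`.
#' @export
atom_feature_spec <- function(featurizers = NULL,
                              include_partial_charge = TRUE,
                              element_set = c("C", "N", "O", "S", "P",
                                              "F", "Cl", "Br", "I")) {
  if (is.null(featurizers)) {
    featurizers <- c("element", "degree", "formal_charge", "hybridization", "h_count")
    if (include_partial_charge) featurizers <- c(featurizers, "partial_charge")
  }
  known <- c("element", "degree", "formal_charge", "hybridization",
             "h_count", "partial_charge")
  bad <- setdiff(featurizers, known)
  if (length(bad)) {
    if (any(grepl("ring", bad, ignore.case = TRUE))) {
      abort(paste0("ring-membership featurizers are not allowed: the cyclic ",
                   "polymer representation requires that no node can detect ",
                   "the macrocycle (offending: ",
                   paste(bad[grepl("ring", bad, ignore.case = TRUE)], collapse = ", "), ")"),
            "polygcn_validation_error")
    }
    abort(sprintf("unknown featurizer(s): %s", paste(bad, collapse = ", ")),
          "polygcn_validation_error")
  }
  if (anyDuplicated(featurizers)) {
    abort("duplicated featurizer identifiers", "polygcn_validation_error")
  }

  spec <- structure(list(
    featurizers = featurizers,
    element_set = element_set,
    degree_range = 0:5,
    hybridization_set = c("sp", "sp2", "sp3", "other"),
    h_range = 0:4,
    include_partial_charge = "partial_charge" %in% featurizers
  ), class = "atom_feature_spec")
  spec$total_dim <- as.integer(sum(vapply(featurizers, featurizer_dim, numeric(1),
                                          spec = spec)))
  spec
}

featurizer_dim <- function(id, spec) {
  switch(id,
    element        = length(spec$element_set) + 1,  # + "other"
    degree         = length(spec$degree_range),
    formal_charge  = 1,
    hybridization  = length(spec$hybridization_set),
    h_count        = length(spec$h_range),
    partial_charge = 1
  )
}

#' @export
print.atom_feature_spec <- function(x, ...) {
  cat(sprintf("<atom_feature_spec> %d featurizers, total_dim = %d\n  %s\n",
              length(x$featurizers), x$total_dim,
              paste(x$featurizers, collapse = " | ")))
  invisible(x)
}

#' Build the node feature matrix for a finalized polymer graph
#'
#' Featurization runs after the polymer topology (linear or cyclic) is
#' final, so neighbor-dependent features — degree, implicit hydrogen count,
#' partial charge — see the actual graph the convolution will run on.
#'
#' @param graph A [molecular_graph] (the builders call this internally; the
#'   exported form supports re-featurizing under a different spec).
#' @param spec An [atom_feature_spec].
#' @return Numeric matrix with one row per node and `spec$total_dim` columns;
#'   every one-hot block sums to 1 (the "other" slot catches
#'   out-of-vocabulary values).
#' @export
featurize_atoms <- function(graph, spec = atom_feature_spec()) {
  stopifnot(inherits(graph, "molecular_graph"), inherits(spec, "atom_feature_spec"))
  a <- graph$atoms
  n <- nrow(a)
  blocks <- lapply(spec$featurizers, function(id) {
    switch(id,
      element = {
        idx <- match(a$element, spec$element_set)
        idx[is.na(idx)] <- length(spec$element_set) + 1L
        one_hot(idx, length(spec$element_set) + 1L)
      },
      degree = {
        d <- pmin(a$degree, max(spec$degree_range))
        one_hot(d + 1L, length(spec$degree_range))
      },
      formal_charge = matrix(as.numeric(a$formal_charge), ncol = 1),
      hybridization = {
        idx <- match(a$hybridization, spec$hybridization_set)
        idx[is.na(idx)] <- length(spec$hybridization_set)
        one_hot(idx, length(spec$hybridization_set))
      },
      h_count = {
        h <- pmin(a$h_count, max(spec$h_range))
        one_hot(h + 1L, length(spec$h_range))
      },
      partial_charge = matrix(a$partial_charge, ncol = 1)
    )
  })
  H0 <- do.call(cbind, blocks)
  dimnames(H0) <- NULL
  stopifnot(ncol(H0) == spec$total_dim)
  H0
}

one_hot <- function(idx, n_levels) {
  m <- matrix(0, nrow = length(idx), ncol = n_levels)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}
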