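#' Parse a polymer repeat unit from marked SMILES
#'
#' A repeat unit is written as an ordinary SMILES string carrying exactly two
#' wildcard atoms (`*`) that mark the backbone attachment points, e.g.
#' `"*CC(*)(C)C(=O)OC"` for methyl methacrylate. Parsing removes the
#' wildcards, validates the remaining structure, and records which heavy
#' atoms flank the two markers; polymer builders later bond those flanking
#' atoms head-to-tail.
#'
#' Hydrogens are implicit throughout: graphs are heavy-atom graphs and the
#' hydrogen count enters as a node feature, recomputed on the final polymer
#' topology (so atoms that gain a backbone bond lose a hydrogen).
#'
#' @param smiles SMILES string with exactly two `*` attachment markers.
#' @param name Optional human-readable label (defaults to the SMILES).
#' @return An object of class `repeat_unit` with elements `smiles`, `name`,
#'   `atoms` (data frame: `element`, `formal_charge`), `bonds` (data frame:
#'   `i`, `j`, `order`, 1-based, each bond stored once), `attach` (the two
#'   flanking heavy-atom indices, in marker order) and `k` (heavy-atom
#'   count).
#' @examples
#' mma <- parse_repeat_unit("*CC(*)(C)C(=O)OC", name = "methyl methacrylate")
#' mma$k  # 7 heavy atoms
#' @export
parse_repeat_unit <- function(smiles, name = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    abort("`smiles` must be a single non-empty string", "polygcn_validation_error")
  }

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      abort(sprintf("could not parse SMILES '%s': %s", smiles, conditionMessage(e)),
            "polygcn_parse_error")
    }
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  # V2000 charge field (atom block column "C5"): 0 none, 1..3 = +3..+1,
  # 5..7 = -1..-3, 4 = radical.
  charge_code <- if ("C5" %in% colnames(ab)) ab[, "C5"] else rep(0, nrow(ab))
  code_map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  formal_charge <- unname(code_map[as.character(charge_code)])
  formal_charge[is.na(formal_charge)] <- 0

  bonds <- data.frame(
    i = as.integer(bb[, 1]), j = as.integer(bb[, 2]), order = as.numeric(bb[, 3])
  )

  markers <- which(elements == "*" | elements == "R")
  if (length(markers) != 2L) {
    abort(sprintf(
      "repeat unit must carry exactly 2 attachment markers '*', found %d in '%s'",
      length(markers), smiles), "polygcn_validation_error")
  }

  # each marker must sit on exactly one heavy atom
  attach_raw <- vapply(markers, function(m) {
    nb <- c(bonds$j[bonds$i == m], bonds$i[bonds$j == m])
    nb <- setdiff(nb, markers)
    if (length(nb) != 1L) {
      abort(sprintf("attachment marker %d must bond exactly one heavy atom", m),
            "polygcn_validation_error")
    }
    nb
  }, integer(1))

  keep <- setdiff(seq_along(elements), markers)
  if (length(keep) == 0L) {
    abort("repeat unit has no heavy atoms besides the markers", "polygcn_validation_error")
  }
  remap <- integer(length(elements))
  remap[keep] <- seq_along(keep)

  bonds_heavy <- bonds[!(bonds$i %in% markers) & !(bonds$j %in% markers), , drop = FALSE]
  bonds_heavy$i <- remap[bonds_heavy$i]
  bonds_heavy$j <- remap[bonds_heavy$j]
  rownames(bonds_heavy) <- NULL

  unit <- structure(list(
    smiles = smiles,
    name = name,
    atoms = data.frame(element = elements[keep], formal_charge = formal_charge[keep]),
    bonds = bonds_heavy,
    attach = remap[attach_raw],
    k = length(keep)
  ), class = "repeat_unit")
  unit
}

#' @export
print.repeat_unit <- function(x, ...) {
  cat(sprintf("<repeat_unit> %s\n  SMILES: %s\n  heavy atoms: %d, bonds: %d, attachment atoms: %s\n",
              x$name, x$smiles, x$k, nrow(x$bonds), paste(x$attach, collapse = ", ")))
  invisible(x)
}

is_repeat_unit <- function(x) inherits(x, "repeat_unit")

as_repeat_unit <- function(x, name = NULL) {
  if (is_repeat_unit(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(parse_repeat_unit(x, name = if (is.null(name)) x else name))
  }
  abort("expected a repeat_unit or a SMILES string", "polygcn_validation_error")
}
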