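#' Hashed circular fingerprint from a SMILES string
#'
#' Morgan-style extended-connectivity fingerprint: each atom starts from an
#' invariant built from its element, heavy-atom degree and total bond
#' order, and the invariants are iteratively rehashed with the sorted
#' (bond-order, neighbour-invariant) pairs of the atom's neighbourhood,
#' once per radius shell. Every atom environment at every radius (0 to
#' `radius`) is hashed onto a bit in \[0, n_bits). Because the invariants
#' are order-independent, two SMILES spellings of the same molecule (e.g.
#' aromatic and kekulized benzene) map to the same bitset.
#'
#' SMILES parsing relies on the ChemmineR/ChemmineOB stack (suggested
#' dependencies); hydrogens are implicit and do not contribute atoms.
#'
#' @param smiles a SMILES string.
#' @param radius neighbourhood radius in bonds (default 2, ECFP4-like).
#' @param n_bits fingerprint length (default 2048).
#' @param molecule_id identifier; defaults to the SMILES itself.
#' @return A [fingerprint()].
#' @export
fingerprint_from_smiles <- function(smiles, radius = 2, n_bits = 2048,
                                    molecule_id = smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprint_from_smiles needs the ChemmineR and ChemmineOB packages")
  }
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    stop("smiles must be a single non-empty string")
  }
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) < 1) stop("unparsable SMILES: ", smiles)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  n_atoms <- length(elements)
  if (n_atoms == 0) stop("unparsable SMILES: ", smiles)
  # adjacency with bond orders
  nbrs <- vector("list", n_atoms)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (r in seq_len(nrow(bb))) {
      i <- bb[r, 1]; j <- bb[r, 2]; o <- bb[r, 3]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
    }
  }
  degree <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bondsum <- vapply(nbrs, function(x) if (is.null(x)) 0 else sum(x[, 2]), numeric(1))
  inv <- mapply(function(el, dg, bs) {
    hash_ints(c(utf8ToInt(el), 257L, dg, as.integer(round(bs * 10))))
  }, elements, degree, bondsum, USE.NAMES = FALSE)
  bits <- inv %% n_bits
  if (radius > 0) {
    for (r in seq_len(radius)) {
      inv_new <- vapply(seq_len(n_atoms), function(i) {
        nb <- nbrs[[i]]
        if (is.null(nb)) return(hash_ints(c(inv[i], 0L)))
        env <- nb[order(nb[, 2], inv[nb[, 1]]), , drop = FALSE]
        hash_ints(c(inv[i], as.integer(t(cbind(round(env[, 2] * 10),
                                               inv[env[, 1]])))))
      }, numeric(1))
      inv <- inv_new
      bits <- c(bits, inv %% n_bits)
    }
  }
  fingerprint(molecule_id, unique(as.integer(bits)), n_bits = n_bits)
}

# Deterministic polynomial hash of an integer vector onto [0, 2^31 - 2].
hash_ints <- function(x) {
  p <- 2147483647  # 2^31 - 1 (Mersenne prime)
  h <- 7
  for (v in as.numeric(x)) {
    h <- (h * 31 + (v %% p)) %% p
  }
  h
}

#' Read a SMILES file
#'
#' One molecule per line, `smiles<TAB>id` (id optional; the SMILES string
#' is used when absent). Empty lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return Data frame with columns `smiles`, `molecule_id`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no molecules in ", path)
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1),
    molecule_id = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                         character(1)),
    stringsAsFactors = FALSE)
}
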