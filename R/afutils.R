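# Interface utilities for predicted complexes: interface extraction and
# the average interface-PAE model-selection score.

#' Interface residues between two chain groups
#'
#' A residue belongs to the interface when any of its heavy atoms lies
#' within `cutoff` of any heavy atom of the other side.
#'
#' @param model a `Structure`
#' @param chains_a,chains_b chain identifier sets for the two sides
#' @param cutoff distance cutoff in A (default 10)
#' @return list with data frames `a` and `b` (columns `chain`, `res_seq`,
#'   `icode`), one row per interface residue of each side
#' @export
interface_residues <- function(model, chains_a, chains_b, cutoff = 10) {
  a <- model$atoms
  for (ch in c(chains_a, chains_b))
    if (!any(a$chain == ch)) stop("unknown chain: ", ch)
  ia <- which(a$chain %in% chains_a)
  ib <- which(a$chain %in% chains_b)
  A <- as.matrix(a[ia, c("x", "y", "z")])
  B <- as.matrix(a[ib, c("x", "y", "z")])
  # pairwise squared distances (atom counts here are modest)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  hit <- d2 <= cutoff^2
  resdf <- function(idx, any_hit) {
    sub <- a[idx[any_hit], c("chain", "res_seq", "icode"), drop = FALSE]
    unique(sub[order(sub$chain, sub$res_seq, sub$icode), , drop = FALSE])
  }
  list(a = resdf(ia, rowSums(hit) > 0), b = resdf(ib, colSums(hit) > 0))
}

#' Parse a predicted-aligned-error (PAE) matrix
#'
#' JSON dialect `{"pae": [[...]], "chains": "AAB..."}`: an n x n matrix of
#' PAE values (A) and a string mapping each residue index to its chain.
#'
#' @param x path to a JSON file or a JSON string
#' @return list with `n`, `values` (n x n matrix) and `chains`
#'   (character vector of length n)
#' @export
parse_pae <- function(x) {
  if (length(x) == 1 && !grepl("[{\n]", x) && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(x)
  m <- as.matrix(obj$pae)
  if (nrow(m) != ncol(m)) stop("PAE matrix must be square")
  if (any(m < 0)) stop("PAE values must be >= 0")
  chains <- strsplit(obj$chains, "")[[1]]
  if (length(chains) != nrow(m))
    stop("chain string length must equal PAE dimension")
  list(n = nrow(m), values = unname(m), chains = chains)
}

# residue order of a structure (one row per residue, in atom order)
residue_index <- function(model) {
  a <- model$atoms
  key <- residue_key(a)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], res_seq = a$res_seq[first],
             icode = a$icode[first], key = key[first],
             stringsAsFactors = FALSE)
}

#' Average interface PAE of a predicted complex model
#'
#' Mean predicted aligned error over cross-chain residue pairs (i in the
#' A-side interface, j in the B-side interface), symmetrized as
#' `(pae[i,j] + pae[j,i]) / 2`.  Lower is better; used to select among
#' candidate predicted complex models.
#'
#' @param model a `Structure`
#' @param pae a [parse_pae()] result (residue order must match the model)
#' @param chains_a,chains_b chain sets of the two sides
#' @param cutoff interface cutoff in A (default 10)
#' @return the score in A
#' @export
interface_pae <- function(model, pae, chains_a, chains_b, cutoff = 10) {
  res <- residue_index(model)
  if (nrow(res) != pae$n)
    stop("PAE dimension (", pae$n, ") does not match model residue count (",
         nrow(res), ")")
  if (!all(res$chain == pae$chains))
    stop("PAE chain string does not match model chain sequence")
  ir <- interface_residues(model, chains_a, chains_b, cutoff = cutoff)
  ia <- match(paste(ir$a$chain, ir$a$res_seq, ir$a$icode, sep = "|"), res$key)
  ib <- match(paste(ir$b$chain, ir$b$res_seq, ir$b$icode, sep = "|"), res$key)
  if (!length(ia) || !length(ib))
    stop("empty interface: chains are not in contact at this cutoff")
  mean((pae$values[ia, ib, drop = FALSE] +
          t(pae$values[ib, ia, drop = FALSE])) / 2)
}
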