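#' @useDynLib dockmapr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dist optim rnorm runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

.atype_levels <- c("C_aliph", "C_arom", "N_don", "O_acc", "S", "P")

new_structure <- function(atoms, id = "structure") {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, id = id), class = "Structure")
}

#' Number of atoms in a structure
#' @param s a `Structure` or `ParamStructure`
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Atom coordinates as an n x 3 matrix
#' @param s a `Structure` or `ParamStructure`
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates
#' @param s a `Structure`; `value` an n x 3 matrix
#' @param value new n x 3 coordinate matrix
#' @export
`coords<-` <- function(s, value) {
  stopifnot(is.matrix(value), nrow(value) == n_atoms(s), ncol(value) == 3)
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<%s> '%s': %d atoms, chains %s\n",
              class(x)[1], x$id, n_atoms(x),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Read a structure from PDB-format text
#'
#' Parses fixed-width `ATOM`/`HETATM` records.  Default filters reproduce a
#' heavy-atom model: waters and hydrogens are dropped, and where alternate
#' locations are present only the highest-occupancy altloc is kept (ties
#' resolved in favour of altloc `A`).
#'
#' @param x path to a PDB file, or a character vector of PDB lines (a single
#'   string with embedded newlines is also accepted)
#' @param id label for the structure; defaults to the file name or "pdb"
#' @param drop_waters drop water residues (default `TRUE`)
#' @param drop_hydrogens drop H/D atoms (default `TRUE`)
#' @param hetero keep HETATM records (default `TRUE`)
#' @param chains optional chain filter
#' @param res_range optional `c(lo, hi)` residue-number filter
#' @return a `Structure`
#' @export
read_pdb <- function(x, id = NULL, drop_waters = TRUE, drop_hydrogens = TRUE,
                     hetero = TRUE, chains = NULL, res_range = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    if (is.null(id)) id <- basename(x)
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
    if (is.null(id)) id <- "pdb"
  }
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop("no atoms: no ATOM/HETATM records found")
  sub <- lines[keep]
  bad <- which(nchar(sub) < 54)
  if (length(bad))
    stop(sprintf("malformed PDB record at line %d (record too short)",
                 keep[bad[1]]))
  f <- function(a, b) substr(sub, a, b)
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(f(a, b)))
    bad <- which(is.na(v) & trimws(f(a, b)) != "")
    if (length(bad))
      stop(sprintf("malformed PDB record at line %d (bad %s field)",
                   keep[bad[1]], what))
    v
  }
  atoms <- data.frame(
    serial = num(7, 11, "serial"),
    name = trimws(f(13, 16)),
    altloc = trimws(f(17, 17)),
    res_name = trimws(f(18, 20)),
    chain = trimws(f(22, 22)),
    res_seq = num(23, 26, "resSeq"),
    icode = trimws(f(27, 27)),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = ifelse(is.na(num(55, 60, "occupancy")), 1,
                       num(55, 60, "occupancy")),
    element = toupper(trimws(substr(paste0(sub, "  "), 77, 78))),
    is_hetero = rec[keep] == "HETATM",
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("malformed PDB record: non-finite coordinates")
  # element inference from the atom name when column 77-78 is blank
  blank <- atoms$element == ""
  if (any(blank)) {
    nm <- gsub("^[0-9']+", "", atoms$name[blank])
    atoms$element[blank] <- toupper(substr(nm, 1, 1))
  }
  if (drop_waters) atoms <- atoms[!(atoms$res_name %in% .water_names), ]
  if (drop_hydrogens) atoms <- atoms[!(atoms$element %in% c("H", "D")), ]
  if (!hetero) atoms <- atoms[!atoms$is_hetero, ]
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, ]
  if (!is.null(res_range))
    atoms <- atoms[atoms$res_seq >= res_range[1] & atoms$res_seq <= res_range[2], ]
  if (!nrow(atoms)) stop("no atoms: selection/filters left an empty structure")
  # altloc policy: per atom site keep the highest occupancy; ties -> 'A'
  if (any(atoms$altloc != "")) {
    key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$name, sep = "|")
    ord <- order(key, -atoms$occupancy,
                 atoms$altloc != "A", atoms$altloc, seq_len(nrow(atoms)))
    atoms <- atoms[ord, ]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$res_seq, atoms$icode,
                                     atoms$name, sep = "|")), ]
    atoms <- atoms[order(atoms$serial), ]
  }
  rownames(atoms) <- NULL
  new_structure(atoms, id)
}

#' Write a structure as PDB-format text
#'
#' @param s a `Structure`
#' @param path optional output file; when given the text is also written there
#' @return character vector of PDB lines, invisibly when `path` is given
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  if (!nrow(a)) stop("cannot write an empty structure")
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("coordinate magnitude >= 10000 A overflows the PDB coordinate field")
  # names of <4 characters conventionally start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               paste0(" ", sprintf("%-3s", a$name)))
  al <- if (is.null(a$altloc)) rep("", nrow(a)) else a$altloc
  ic <- if (is.null(a$icode)) rep("", nrow(a)) else a$icode
  occ <- if (is.null(a$occupancy)) rep(1, nrow(a)) else a$occupancy
  lines <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$is_hetero, "HETATM", "ATOM"),
                   a$serial %% 100000, nm,
                   al, a$res_name,
                   a$chain, a$res_seq %% 10000, ic,
                   a$x, a$y, a$z, occ, 0, a$element)
  out <- c(lines, "TER", "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Select atoms by chain, residue range, atom name
#'
#' @param s a `Structure`
#' @param chains,res_range,names,hetero optional filters; `res_range` is
#'   `c(lo, hi)` in author numbering
#' @return a `Structure` with the matching atoms (error when empty)
#' @export
select_atoms <- function(s, chains = NULL, res_range = NULL, names = NULL,
                         hetero = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(res_range))
    keep <- keep & a$res_seq >= res_range[1] & a$res_seq <= res_range[2]
  if (!is.null(names)) keep <- keep & a$name %in% names
  if (!is.null(hetero)) keep <- keep & a$is_hetero == hetero
  if (!any(keep)) stop("no atoms: selection matched nothing")
  out <- s
  out$atoms <- a[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Packaged per-atom parameter table
#'
#' Columns: `res_name`, `atom_name`, `radius` (A), `charge` (e), `atype`.
#' Rows with `res_name == "."` are element fallbacks keyed by element symbol
#' (`"X"` is the last-resort default).
#' @export
default_param_table <- function() {
  read.delim(system.file("extdata", "atom_params.tsv", package = "dockmapr"),
             stringsAsFactors = FALSE)
}

#' Packaged coarse atom-type contact matrix
#'
#' Symmetric 6x6 matrix over the coarse types (negative entries are
#' attractive) used by the pairwise-potential grid channels.
#' @export
pair_contact_matrix <- function() {
  t <- read.delim(system.file("extdata", "pair_contact.tsv",
                              package = "dockmapr"),
                  check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(t[, -1])
  rownames(m) <- t$atype
  m
}

#' Assign per-atom radius, partial charge and coarse type
#'
#' Lookup order is (res_name, atom name), then element fallback.  In strict
#' mode any atom missing from the table is an error; otherwise the element
#' fallback (or the generic default) is used and a message is logged.
#'
#' @param s a `Structure`
#' @param table a parameter table (see [default_param_table()])
#' @param strict error on atoms with no residue-specific entry
#' @return a `ParamStructure`: the structure with `radius`, `charge`,
#'   `atype` columns added
#' @export
assign_params <- function(s, table = default_param_table(), strict = FALSE) {
  a <- s$atoms
  key <- paste(a$res_name, a$name, sep = "|")
  tkey <- paste(table$res_name, table$atom_name, sep = "|")
  i <- match(key, tkey)
  miss <- is.na(i)
  if (any(miss)) {
    if (strict) {
      bad <- unique(paste0(a$res_name[miss], ":", a$name[miss]))
      stop("assign_params (strict): no parameters for atoms ",
           paste(bad, collapse = ", "))
    }
    fb <- match(paste(".", a$element[miss], sep = "|"), tkey)
    fb[is.na(fb)] <- match(".|X", tkey)
    i[miss] <- fb
    message(sprintf("assign_params: element-fallback parameters for %d atom(s)",
                    sum(miss)))
  }
  a$radius <- table$radius[i]
  a$charge <- table$charge[i]
  a$atype <- table$atype[i]
  out <- new_structure(a, s$id)
  class(out) <- c("ParamStructure", "Structure")
  out
}

is_param_structure <- function(s) inherits(s, "ParamStructure")
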