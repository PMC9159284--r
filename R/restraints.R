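# Pairwise distance restraints with k-of-n group semantics.
#
# JSON dialect:
# {"groups": [{"required": k,
#              "restraints": [{"rec": "A.85.CB", "lig": "C.119", "dmin": 2,
#                              "dmax": 10}, ...]}, ...]}
# A selector is "chain.res_seq[.atom]"; when the atom is omitted the
# default is CB, or CA for glycine.

parse_selector <- function(s) {
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) > 3 || parts[1] == "" ||
      is.na(suppressWarnings(as.integer(parts[2]))))
    stop("unknown selector syntax: '", s, "' (expected chain.res[.atom])")
  list(chain = parts[1], res_seq = as.integer(parts[2]),
       atom = if (length(parts) == 3) parts[3] else NA_character_)
}

selector_string <- function(sel) {
  if (is.na(sel$atom)) paste(sel$chain, sel$res_seq, sep = ".")
  else paste(sel$chain, sel$res_seq, sel$atom, sep = ".")
}

new_restraint <- function(rec, lig, dmin, dmax) {
  if (!(dmin >= 0 && dmin < dmax))
    stop("invalid restraint bounds: need 0 <= dmin < dmax (got ",
         dmin, ", ", dmax, ")")
  list(rec = rec, lig = lig, dmin = dmin, dmax = dmax)
}

new_restraint_group <- function(restraints, required) {
  if (required < 1 || required > length(restraints))
    stop("restraint group: required must satisfy 1 <= k <= ",
         length(restraints), " (got ", required, ")")
  list(restraints = restraints, required = as.integer(required))
}

new_restraint_set <- function(groups) {
  if (!length(groups)) stop("restraint set must contain at least one group")
  structure(list(groups = groups), class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat(sprintf("<RestraintSet> %d group(s): %s\n", length(x$groups),
              paste(vapply(x$groups, function(g)
                sprintf("%d-of-%d", g$required, length(g$restraints)), ""),
                collapse = ", ")))
  invisible(x)
}

#' Parse a restraint file (JSON dialect)
#'
#' @param x path to a JSON file or a JSON string
#' @return a `RestraintSet`
#' @export
parse_restraints <- function(x) {
  if (length(x) == 1 && !grepl("[{\n]", x) && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (is.null(obj$groups)) stop("restraint JSON must have a 'groups' array")
  groups <- lapply(obj$groups, function(g) {
    if (is.null(g$required) || is.null(g$restraints))
      stop("each restraint group needs 'required' and 'restraints'")
    rl <- lapply(g$restraints, function(r) {
      new_restraint(parse_selector(r$rec), parse_selector(r$lig),
                    as.numeric(r$dmin), as.numeric(r$dmax))
    })
    new_restraint_group(rl, g$required)
  })
  new_restraint_set(groups)
}

#' Generate a restraint set from residue pairs
#'
#' Builds a single k-of-n group, the shape emitted by interactive
#' restraint generators for cross-linking or mutagenesis data.
#'
#' @param pairs character vector `"A.85:C.119"` (receptor:ligand
#'   selectors) or a list of `list(rec=, lig=)` selector strings
#' @param dmin,dmax distance bounds in A
#' @param k number of member restraints that must hold (k-of-n)
#' @return a `RestraintSet` with one group
#' @export
generate_restraints <- function(pairs, dmin, dmax, k = 1) {
  if (!length(pairs)) stop("pairs must be non-empty")
  if (k < 1) stop("restraint group: required must satisfy 1 <= k")
  rl <- lapply(pairs, function(p) {
    if (is.character(p)) {
      halves <- strsplit(p, ":", fixed = TRUE)[[1]]
      if (length(halves) != 2)
        stop("pair must be 'recsel:ligsel', got '", p, "'")
      new_restraint(parse_selector(halves[1]), parse_selector(halves[2]),
                    dmin, dmax)
    } else {
      new_restraint(parse_selector(p$rec), parse_selector(p$lig), dmin, dmax)
    }
  })
  new_restraint_set(list(new_restraint_group(rl, k)))
}

#' Serialize a restraint set to the JSON dialect
#' @param rs a `RestraintSet`
#' @param path optional output file
#' @export
write_restraints <- function(rs, path = NULL) {
  obj <- list(groups = lapply(rs$groups, function(g) {
    list(required = g$required,
         restraints = lapply(g$restraints, function(r) {
           list(rec = selector_string(r$rec), lig = selector_string(r$lig),
                dmin = r$dmin, dmax = r$dmax)
         }))
  }))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# resolve a selector to one atom row index; default atom CB (CA for GLY)
resolve_atom <- function(s, sel) {
  a <- s$atoms
  i <- which(a$chain == sel$chain & a$res_seq == sel$res_seq)
  if (!length(i))
    stop("restraint selection matches no atom: ", selector_string(sel))
  atom <- sel$atom
  if (is.na(atom)) atom <- if (a$res_name[i[1]] == "GLY") "CA" else "CB"
  j <- i[a$name[i] == atom]
  if (!length(j))
    stop("restraint selection matches no atom: ",
         selector_string(list(chain = sel$chain, res_seq = sel$res_seq,
                              atom = atom)))
  j[1]
}

resolve_restraint_selections <- function(rs, rec, lig) {
  rec_xyz <- lapply(rs$groups, function(g)
    lapply(g$restraints, function(r) coords(rec)[resolve_atom(rec, r$rec), ]))
  lig_idx <- lapply(rs$groups, function(g)
    lapply(g$restraints, function(r) resolve_atom(lig, r$lig)))
  list(rec_xyz = rec_xyz, lig_idx = lig_idx)
}

#' Evaluate a restraint set on a posed complex
#'
#' A restraint holds iff `dmin <= d <= dmax` for its selected atom pair; a
#' group holds iff at least `required` members hold; the set holds iff
#' every group holds (AND across groups).
#'
#' @param rec receptor `Structure`
#' @param lig posed ligand `Structure` (already transformed), or the
#'   ligand plus a `pose` to apply
#' @param rs a `RestraintSet`
#' @param pose optional `Pose` applied to `lig` first
#' @return list with `ok` flag and a per-group `tally` data frame
#'   (`group`, `required`, `n_satisfied`, `ok`)
#' @export
satisfied <- function(rec, lig, rs, pose = NULL) {
  if (!is.null(pose)) lig <- pose_ligand(pose, lig)
  tally <- do.call(rbind, lapply(seq_along(rs$groups), function(gi) {
    g <- rs$groups[[gi]]
    nsat <- sum(vapply(g$restraints, function(r) {
      a <- coords(rec)[resolve_atom(rec, r$rec), ]
      b <- coords(lig)[resolve_atom(lig, r$lig), ]
      d <- sqrt(sum((a - b)^2))
      d >= r$dmin && d <= r$dmax
    }, logical(1)))
    data.frame(group = gi, required = g$required, n_satisfied = nsat,
               ok = nsat >= g$required)
  }))
  list(ok = all(tally$ok), tally = tally)
}

#' Filter a pose list by a restraint set
#'
#' Re-checks the satisfaction predicate pose by pose; equivalent to the
#' in-sweep filtering of [dock_rigid()] but usable post hoc.
#' @param poses a `PoseList`
#' @param rec,lig the docked structures
#' @param rs a `RestraintSet`
#' @export
filter_poses <- function(poses, rec, lig, rs) {
  keep <- vapply(poses$poses, function(p)
    satisfied(rec, lig, rs, pose = p)$ok, logical(1))
  out <- poses
  out$poses <- poses$poses[keep]
  for (i in seq_along(out$poses)) out$poses[[i]]$rank <- i
  out
}
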