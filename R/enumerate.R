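# Nitrogen-feature enumeration over carbon ring systems.
#
# Two feature kinds exist: RING_N replaces a ring carbon by nitrogen, and
# EXO_NH2 replaces one hydrogen of a ring carbon by a primary amino group.
# Every scaffold carries one or two features, applied simultaneously, and
# must pass three exclusion rules: no hydrazine (N-N bond), no aminal
# (carbon with two nitrogen neighbors), no quaternary nitrogen (four heavy
# neighbors). Survivors are deduplicated up to graph symmetry.

.AMINE_ORDER <- c("N", "NH", "NH2")

#' Amine class of a nitrogen atom
#'
#' Classifies a nitrogen by heavy-atom degree: three heavy neighbors is a
#' tertiary amine (`"N"`), two a secondary amine (`"NH"`), one a primary
#' amine (`"NH2"`).
#'
#' @param g A `molgraph`.
#' @param n_index Atom index of a nitrogen in `g`.
#' @return One of `"N"`, `"NH"`, `"NH2"`.
#' @export
amine_class <- function(g, n_index) {
  if (g$elements[n_index] != "N") {
    stop("atom ", n_index, " is ", g$elements[n_index], ", not nitrogen")
  }
  deg <- atom_degrees(g)[n_index]
  switch(as.character(deg), "3" = "N", "2" = "NH", "1" = "NH2",
         stop("nitrogen with unsupported heavy degree ", deg))
}

#' Chemical-validity check with violation report
#'
#' Tests the three exclusion rules that define the enumerated chemical
#' space: (a) hydrazine — a bond joining two nitrogens; (b) aminal — a
#' carbon with two or more nitrogen neighbors (covering ring N-C-N, ring N
#' adjacent to an aminomethine carbon, and geminal diamines uniformly);
#' (c) quaternary nitrogen — a nitrogen with four heavy neighbors.
#'
#' @param g A `molgraph`.
#' @return Logical scalar; `FALSE` carries attributes `rule` (the first
#'   violated rule name) and `atoms` (offending atom indices).
#' @examples
#' is_valid_scaffold(fixture_molecule("piperazine"))  # TRUE
#' @export
is_valid_scaffold <- function(g) {
  is_n <- g$elements == "N"
  b <- g$bonds
  nn <- which(is_n[b[, 1]] & is_n[b[, 2]])
  if (length(nn) > 0L) {
    return(structure(FALSE, rule = "hydrazine", atoms = as.integer(b[nn[1], ])))
  }
  n_neighbors <- tabulate(c(b[is_n[b[, 2]], 1], b[is_n[b[, 1]], 2]),
                          nbins = length(g$elements))
  aminal <- which(!is_n & n_neighbors >= 2L)
  if (length(aminal) > 0L) {
    return(structure(FALSE, rule = "aminal", atoms = aminal[1]))
  }
  deg <- atom_degrees(g)
  quat <- which(is_n & deg >= 4L)
  if (length(quat) > 0L) {
    return(structure(FALSE, rule = "quaternary", atoms = quat[1]))
  }
  TRUE
}

#' Candidate nitrogen-feature sets for a skeleton
#'
#' Lists every size-`k` set of nitrogen features satisfying the per-feature
#' site constraints: RING_N requires ring degree <= 3 (a spiro center would
#' give a quaternary nitrogen); EXO_NH2 requires a carbon with at least one
#' hydrogen to exchange (ring degree <= 3), bridgeheads included. A site
#' carries at most one feature, so geminal bis-NH2 and N-with-NH2 overlaps
#' are never generated.
#'
#' @param skeleton A `carbon_skeleton`.
#' @param k Number of features, 1 or 2.
#' @return List of feature sets; each set is a list of features, each
#'   feature a list with `kind` (`"RING_N"` or `"EXO_NH2"`) and `site`.
#' @export
feature_candidates <- function(skeleton, k) {
  stopifnot(k %in% c(1L, 2L))
  deg <- atom_degrees(skeleton$graph)
  sites <- which(deg <= 3L)  # same constraint for both feature kinds
  feat <- function(kind, site) list(kind = kind, site = site)
  if (k == 1L) {
    out <- c(lapply(sites, function(s) list(feat("RING_N", s))),
             lapply(sites, function(s) list(feat("EXO_NH2", s))))
    return(out)
  }
  out <- list()
  ns <- length(sites)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (j > i) {
        out[[length(out) + 1L]] <- list(feat("RING_N", sites[i]),
                                        feat("RING_N", sites[j]))
        out[[length(out) + 1L]] <- list(feat("EXO_NH2", sites[i]),
                                        feat("EXO_NH2", sites[j]))
      }
      if (j != i) {
        # mixed pairs need both orientations: the two kinds are distinct
        out[[length(out) + 1L]] <- list(feat("RING_N", sites[i]),
                                        feat("EXO_NH2", sites[j]))
      }
    }
  }
  out
}

.apply_features <- function(graph, features) {
  g <- graph
  for (f in features) {
    if (f$kind == "RING_N") {
      g$elements[f$site] <- "N"
    } else {
      g$elements <- c(g$elements, "N")
      g$bonds <- rbind(g$bonds, c(f$site, length(g$elements)))
    }
  }
  g$bonds <- .normalize_bonds(g$bonds)
  g
}

.n_profile <- function(g) {
  n_idx <- which(g$elements == "N")
  classes <- vapply(n_idx, function(i) amine_class(g, i), character(1))
  classes <- classes[order(match(classes, .AMINE_ORDER))]
  list(classes = classes, column_key = paste(classes, collapse = "/"))
}

.new_scaffold <- function(skeleton, features, graph) {
  prof <- .n_profile(graph)
  structure(list(parent = skeleton$name,
                 ring_type = skeleton$ring_type,
                 ring_sizes = skeleton$ring_sizes,
                 features = features,
                 graph = graph,
                 key = canonical_key(graph),
                 smiles = to_smiles(graph),
                 profile = prof$classes,
                 column_key = prof$column_key,
                 formula = mol_formula(graph)),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("<scaffold> %s  %s  [%s on %s, rings %s]  MW %.2f\n",
              x$smiles, x$formula$string, x$column_key, x$parent,
              paste(x$ring_sizes, collapse = ","), x$formula$weight))
  invisible(x)
}

#' Enumerate all valid scaffolds of one carbon skeleton
#'
#' Applies every 1- and 2-feature candidate set, discards graphs violating
#' the hydrazine, aminal or quaternary-nitrogen rules, and deduplicates the
#' survivors by canonical key, so symmetry-equivalent placements count once.
#'
#' @param skeleton A `carbon_skeleton`.
#' @return List of `scaffold` objects, sorted by canonical key.
#' @examples
#' sk <- generate_monocycles(6)[[1]]
#' length(enumerate_scaffolds(sk))  # 8, one of which is piperazine
#' @export
enumerate_scaffolds <- function(skeleton) {
  candidates <- c(feature_candidates(skeleton, 1L),
                  feature_candidates(skeleton, 2L))
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (features in candidates) {
    g <- .apply_features(skeleton$graph, features)
    if (!isTRUE(is_valid_scaffold(g))) next
    key <- canonical_key(g)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <- .new_scaffold(skeleton, features, g)
  }
  out[order(vapply(out, function(s) s$key, character(1)))]
}

#' Enumerate scaffolds over a set of skeletons
#'
#' Union of the per-skeleton enumerations, globally deduplicated by
#' canonical key. Distinct parent ring systems cannot produce the same
#' scaffold graph (the parent skeleton is recoverable from the scaffold),
#' so a cross-skeleton collision indicates an internal error and aborts.
#'
#' @param skeletons Non-empty list of `carbon_skeleton` objects.
#' @return List of `scaffold` objects, sorted by canonical key.
#' @examples
#' \donttest{
#' scaffolds <- enumerate_all(generate_all_skeletons(5:7))
#' length(scaffolds)  # 1139
#' }
#' @export
enumerate_all <- function(skeletons) {
  if (length(skeletons) == 0L) stop("skeleton list must be non-empty")
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (sk in skeletons) {
    for (sc in enumerate_scaffolds(sk)) {
      if (!is.null(seen[[sc$key]])) {
        stop("canonical-key collision across skeletons ('", seen[[sc$key]],
             "' vs '", sk$name, "'): enumeration invariant violated")
      }
      seen[[sc$key]] <- sk$name
      out[[length(out) + 1L]] <- sc
    }
  }
  out[order(vapply(out, function(s) s$key, character(1)))]
}

#' Scaffold set as a data frame
#'
#' One row per scaffold with its SMILES, parent skeleton, ring topology,
#' ring sizes, amine-type column key, formula and molecular weight.
#'
#' @param scaffolds List of `scaffold` objects.
#' @return A `data.frame`.
#' @export
scaffold_table <- function(scaffolds) {
  data.frame(
    smiles = vapply(scaffolds, function(s) s$smiles, character(1)),
    parent = vapply(scaffolds, function(s) s$parent, character(1)),
    ring_type = vapply(scaffolds, function(s) s$ring_type, character(1)),
    ring_sizes = vapply(scaffolds, function(s)
      paste(s$ring_sizes, collapse = ","), character(1)),
    n_types = vapply(scaffolds, function(s) s$column_key, character(1)),
    formula = vapply(scaffolds, function(s) s$formula$string, character(1)),
    mw = vapply(scaffolds, function(s) s$formula$weight, numeric(1)),
    key = vapply(scaffolds, function(s) s$key, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a scaffold set as a tab-separated SMILES file
#'
#' One scaffold per line: canonical SMILES, parent skeleton name, ring
#' type, ring sizes, amine-type key, formula, molecular weight (2 dp).
#'
#' @param scaffolds List of `scaffold` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scaffolds <- function(scaffolds, path) {
  df <- scaffold_table(scaffolds)
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%.2f", df$smiles, df$parent,
                   df$ring_type, df$ring_sizes, df$n_types, df$formula, df$mw)
  writeLines(lines, path)
  invisible(path)
}

#' Read a scaffold SMILES file
#'
#' Parses a file written by [write_scaffolds()] (or any file whose first
#' tab-separated column is a SMILES in the supported subset), recomputes
#' each scaffold's canonical key, profile and formula from the parsed
#' graph, and deduplicates by key.
#'
#' @param path Input file path.
#' @return A list with `scaffolds` (list of `scaffold` objects) and
#'   `n_duplicates` (lines dropped by deduplication).
#' @export
read_scaffolds <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  seen <- new.env(parent = emptyenv())
  n_dup <- 0L
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    g <- tryCatch(parse_smiles(fields[1]),
                  error = function(e) stop("line ", ln, ": ", conditionMessage(e)))
    key <- canonical_key(g)
    if (!is.null(seen[[key]])) { n_dup <- n_dup + 1L; next }
    seen[[key]] <- TRUE
    # reconstruct the parent skeleton context from the graph itself
    parent_graph <- .parent_skeleton_graph(g)
    prof <- .n_profile(g)
    out[[length(out) + 1L]] <- structure(list(
      parent = if (length(fields) >= 2L) fields[2] else NA_character_,
      ring_type = classify_ring_type(parent_graph),
      ring_sizes = sssr_sizes(parent_graph),
      features = NULL,
      graph = g,
      key = key,
      smiles = to_smiles(g),
      profile = prof$classes,
      column_key = prof$column_key,
      formula = mol_formula(g)), class = "scaffold")
  }
  list(scaffolds = out[order(vapply(out, function(s) s$key, character(1)))],
       n_duplicates = n_dup)
}

# strip exocyclic NH2 groups and relabel ring N back to C: the parent
# carbon ring system of a scaffold
.parent_skeleton_graph <- function(g) {
  deg <- atom_degrees(g)
  drop <- which(g$elements == "N" & deg == 1L)
  keep <- setdiff(seq_along(g$elements), drop)
  idx <- match(seq_along(g$elements), keep)
  b <- g$bonds
  b <- b[!(b[, 1] %in% drop | b[, 2] %in% drop), , drop = FALSE]
  molgraph(rep("C", length(keep)), matrix(idx[b], ncol = 2))
}
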