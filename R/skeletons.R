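# Saturated mono- and bicyclic carbon ring systems.
#
# The universe of parent frameworks is derived analytically: one cycle per
# allowed ring size, one spiro and one fused skeleton per unordered size
# pair, and every bicyclo[x.y.z] bridge specification (x >= y >= z >= 1)
# whose two smallest rings both have allowed sizes. At circuit rank 2 no
# other topology exists, so this construction is complete.

.ALKANE_NAMES <- c("methane", "ethane", "propane", "butane", "pentane",
                   "hexane", "heptane", "octane", "nonane", "decane",
                   "undecane", "dodecane", "tridecane", "tetradecane",
                   "pentadecane", "hexadecane", "heptadecane", "octadecane",
                   "nonadecane", "icosane")

.alkane <- function(n) {
  if (n < 1L || n > length(.ALKANE_NAMES)) return(paste0("C", n, "-alkane"))
  .ALKANE_NAMES[n]
}

.RING_TYPES <- c("monocyclic", "spirocyclic", "fused", "bridged")

.new_skeleton <- function(graph, ring_type, ring_sizes, name, bridge = NULL) {
  structure(list(graph = graph,
                 ring_type = ring_type,
                 ring_sizes = as.integer(sort(ring_sizes)),
                 name = name,
                 bridge = bridge,
                 key = canonical_key(graph)),
            class = "carbon_skeleton")
}

#' @export
print.carbon_skeleton <- function(x, ...) {
  cat(sprintf("<carbon_skeleton> %s: %s, ring sizes (%s), %d atoms\n",
              x$name, x$ring_type, paste(x$ring_sizes, collapse = ","),
              length(x$graph$elements)))
  invisible(x)
}

.check_sizes <- function(sizes) {
  sizes <- as.integer(sizes)
  if (any(sizes < 3L)) stop("ring sizes must be >= 3 (got ",
                            paste(sizes[sizes < 3L], collapse = ", "), ")")
  sort(unique(sizes))
}

.check_pairs <- function(size_pairs) {
  pairs <- lapply(size_pairs, function(p) {
    p <- as.integer(sort(p))
    if (length(p) != 2L) stop("each size pair must have exactly two sizes")
    if (any(p < 3L)) stop("ring sizes must be >= 3")
    p
  })
  pairs <- unique(pairs)
  pairs[order(vapply(pairs, `[`, integer(1), 1L),
              vapply(pairs, `[`, integer(1), 2L))]
}

#' Generate monocyclic carbon skeletons
#'
#' One cycloalkane ring per requested size.
#'
#' @param sizes Integer vector of ring sizes (each >= 3).
#' @return List of `carbon_skeleton` objects, sorted by size.
#' @examples
#' length(generate_monocycles(c(5, 6, 7)))  # 3
#' @export
generate_monocycles <- function(sizes) {
  sizes <- .check_sizes(sizes)
  lapply(sizes, function(n) {
    .new_skeleton(.ring_molgraph(n), "monocyclic", n,
                  paste0("cyclo", .alkane(n)))
  })
}

.spiro_molgraph <- function(a, b) {
  # ring A is atoms 1..a; ring B reuses atom 1 plus atoms a+1 .. a+b-1
  bonds <- cbind(seq_len(a), c(seq_len(a)[-1], 1L))
  path <- (a + 1L):(a + b - 1L)
  bonds <- rbind(bonds, c(1L, path[1]))
  if (length(path) > 1L) bonds <- rbind(bonds, cbind(path[-length(path)], path[-1]))
  bonds <- rbind(bonds, c(path[length(path)], 1L))
  molgraph(rep("C", a + b - 1L), bonds)
}

#' Generate spirocyclic carbon skeletons
#'
#' One skeleton per unordered size pair: two rings sharing exactly one atom.
#'
#' @param size_pairs List of integer pairs, e.g. `list(c(5, 5), c(5, 6))`.
#' @return List of `carbon_skeleton` objects in sorted pair order.
#' @export
generate_spiro <- function(size_pairs) {
  pairs <- .check_pairs(size_pairs)
  lapply(pairs, function(p) {
    a <- p[1]; b <- p[2]
    name <- paste0("spiro[", a - 1L, ".", b - 1L, "]", .alkane(a + b - 1L))
    .new_skeleton(.spiro_molgraph(a, b), "spirocyclic", p, name)
  })
}

.bicyclo_name <- function(x, y, z) {
  paste0("bicyclo[", x, ".", y, ".", z, "]", .alkane(x + y + z + 2L))
}

#' Generate fused bicyclic carbon skeletons
#'
#' One skeleton per unordered size pair: two rings sharing exactly one edge,
#' i.e. bicyclo[a-2.b-2.0] for ring sizes (a, b).
#'
#' @inheritParams generate_spiro
#' @return List of `carbon_skeleton` objects.
#' @export
generate_fused <- function(size_pairs) {
  pairs <- .check_pairs(size_pairs)
  lapply(pairs, function(p) {
    a <- p[1]; b <- p[2]
    x <- b - 2L; y <- a - 2L
    .new_skeleton(.bicyclo_molgraph(x, y, 0L), "fused", p,
                  .bicyclo_name(x, y, 0L), bridge = c(x, y, 0L))
  })
}

# all (x, y, z) with x >= y >= z >= 1 whose two smallest rings are (a, b):
# ring sizes are y+z+2 and x+z+2 (the third ring x+y+2 is never smaller)
.bridge_specs_for_pair <- function(a, b) {
  specs <- list()
  for (z in seq_len(max(a - 3L, 0L))) {
    y <- a - 2L - z
    x <- b - 2L - z
    if (y >= z && x >= y && x >= 1L) specs[[length(specs) + 1L]] <- c(x, y, z)
  }
  specs
}

#' Generate bridged bicyclic carbon skeletons
#'
#' All bicyclo[x.y.z] bridge specifications with x >= y >= z >= 1 whose two
#' smallest rings (sizes y+z+2 and x+z+2) match a requested size pair,
#' deduplicated by canonical key.
#'
#' @inheritParams generate_spiro
#' @return List of `carbon_skeleton` objects in lexicographic bridge order.
#' @examples
#' # the only C5/C5 bridged system is norbornane
#' generate_bridged(list(c(5, 5)))[[1]]$name  # "bicyclo[2.2.1]heptane"
#' @export
generate_bridged <- function(size_pairs) {
  pairs <- .check_pairs(size_pairs)
  out <- list()
  seen <- character(0)
  for (p in pairs) {
    for (spec in .bridge_specs_for_pair(p[1], p[2])) {
      sk <- .new_skeleton(.bicyclo_molgraph(spec[1], spec[2], spec[3]),
                          "bridged", p, .bicyclo_name(spec[1], spec[2], spec[3]),
                          bridge = spec)
      if (!(sk$key %in% seen)) {
        seen <- c(seen, sk$key)
        out[[length(out) + 1L]] <- sk
      }
    }
  }
  # lexicographic by ring sizes, then bridge spec
  ord <- order(vapply(out, function(s) s$ring_sizes[1], integer(1)),
               vapply(out, function(s) s$ring_sizes[2], integer(1)),
               vapply(out, function(s) s$bridge[1], integer(1)),
               vapply(out, function(s) s$bridge[2], integer(1)),
               vapply(out, function(s) s$bridge[3], integer(1)))
  out[ord]
}

#' Generate the complete skeleton set for a ring-size set
#'
#' Concatenates the monocyclic, spirocyclic, fused and bridged generators
#' over all sizes and unordered size pairs drawn from `sizes`, deduplicates
#' globally by canonical key, and orders deterministically by ring type,
#' ring sizes and name. With the default sizes `{5, 6, 7}` this yields the
#' 24 parent ring systems of the enumerated amine chemical space.
#'
#' @param sizes Integer vector of allowed smallest-ring sizes (default 5:7).
#' @return List of `carbon_skeleton` objects.
#' @examples
#' length(generate_all_skeletons(5:7))  # 24
#' @export
generate_all_skeletons <- function(sizes = 5:7) {
  sizes <- .check_sizes(sizes)
  if (length(sizes) == 0L) stop("at least one ring size is required")
  pairs <- list()
  for (i in seq_along(sizes)) {
    for (j in i:length(sizes)) {
      pairs[[length(pairs) + 1L]] <- c(sizes[i], sizes[j])
    }
  }
  all <- c(generate_monocycles(sizes), generate_spiro(pairs),
           generate_fused(pairs), generate_bridged(pairs))
  keys <- vapply(all, function(s) s$key, character(1))
  all <- all[!duplicated(keys)]
  ord <- order(match(vapply(all, function(s) s$ring_type, character(1)), .RING_TYPES),
               vapply(all, function(s) s$ring_sizes[1], integer(1)),
               vapply(all, function(s) s$ring_sizes[length(s$ring_sizes)], integer(1)),
               vapply(all, function(s) s$name, character(1)))
  all[ord]
}

#' Classify the ring topology of a carbon ring system
#'
#' Uses the branch-vertex signature of the graph, which must be a connected
#' ring system with no acyclic appendages: circuit rank 1 is monocyclic; at
#' circuit rank 2, one atom with four ring bonds is spirocyclic, and two
#' atoms with three ring bonds are fused when adjacent and bridged when not.
#'
#' @param g A `molgraph` satisfying the ring-system invariants.
#' @return One of `"monocyclic"`, `"spirocyclic"`, `"fused"`, `"bridged"`.
#' @export
classify_ring_type <- function(g) {
  validate_molgraph(g)
  n <- length(g$elements)
  m <- nrow(g$bonds)
  rank <- m - n + 1L
  deg <- atom_degrees(g)
  if (any(deg < 2L)) stop("malformed skeleton: atom off-ring (degree < 2)")
  if (rank == 1L) {
    if (any(deg != 2L)) stop("malformed skeleton: monocycle with branch vertex")
    return("monocyclic")
  }
  if (rank != 2L) stop("malformed skeleton: circuit rank ", rank,
                       " (only mono- and bicyclic supported)")
  d4 <- which(deg == 4L)
  d3 <- which(deg == 3L)
  if (length(d4) == 1L && length(d3) == 0L) return("spirocyclic")
  if (length(d4) == 0L && length(d3) == 2L) {
    adjacent <- any(g$bonds[, 1] == d3[1] & g$bonds[, 2] == d3[2])
    return(if (adjacent) "fused" else "bridged")
  }
  stop("malformed skeleton: branch-vertex signature matches no bicyclic topology")
}

# enumerate every simple cycle; feasible because ring systems at circuit
# rank <= 2 carry at most three simple cycles
.simple_cycles <- function(g) {
  n <- length(g$elements)
  adj <- .adjacency(n, g$bonds)
  cycles <- list()
  path <- integer(0)
  on_path <- logical(n)
  extend <- function(start, v) {
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3L) {
        # record once per orientation: require second vertex < last vertex
        if (path[2] < path[length(path)]) {
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (w > start && !on_path[w]) {
        path <<- c(path, w); on_path[w] <<- TRUE
        extend(start, w)
        on_path[w] <<- FALSE; path <<- path[-length(path)]
      }
    }
  }
  for (s in seq_len(n)) {
    path <- s; on_path[] <- FALSE; on_path[s] <- TRUE
    extend(s, s)
  }
  cycles
}

#' Smallest-set-of-smallest-rings sizes of a ring system
#'
#' For a monocycle returns the single ring size; for a bicyclic system the
#' sizes of the two smallest simple cycles (for bicyclo[x.y.z] these are
#' y+z+2 and x+z+2). Computed by exhaustive simple-cycle enumeration, which
#' is exact at circuit rank <= 2.
#'
#' @param g A `molgraph` satisfying the ring-system invariants.
#' @return Sorted integer vector of length 1 (monocyclic) or 2 (bicyclic).
#' @export
sssr_sizes <- function(g) {
  rank <- nrow(g$bonds) - length(g$elements) + 1L
  lens <- sort(vapply(.simple_cycles(g), length, integer(1)))
  if (rank < 1L || rank > 2L) stop("not a mono- or bicyclic ring system")
  lens[seq_len(rank)]
}

#' Write skeletons as a tab-separated SMILES file
#'
#' One record per line: SMILES, name, ring type, comma-separated ring sizes.
#'
#' @param skeletons List of `carbon_skeleton` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_skeletons <- function(skeletons, path) {
  lines <- vapply(skeletons, function(s) {
    paste(to_smiles(s$graph), s$name, s$ring_type,
          paste(s$ring_sizes, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
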