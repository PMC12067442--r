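# Independent oracles used to check the package's graph machinery.
# These deliberately avoid canonical_key() and the package's own cycle
# enumeration: isomorphism and automorphisms are found by exhaustive
# backtracking over vertex bijections, cycles by edge deletion plus
# shortest-path search in igraph.

adjacency_matrix <- function(g) {
  n <- length(g$elements)
  A <- matrix(FALSE, n, n)
  A[g$bonds] <- TRUE
  A[g$bonds[, 2:1, drop = FALSE]] <- TRUE
  A
}

# exhaustive element- and adjacency-preserving bijection search
perm_isomorphic <- function(g1, g2) {
  n <- length(g1$elements)
  if (n != length(g2$elements)) return(FALSE)
  if (!identical(sort(g1$elements), sort(g2$elements))) return(FALSE)
  d1 <- atom_degrees(g1); d2 <- atom_degrees(g2)
  if (!identical(sort(d1), sort(d2))) return(FALSE)
  A1 <- adjacency_matrix(g1); A2 <- adjacency_matrix(g2)
  map <- rep(NA_integer_, n); used <- logical(n)
  bt <- function(i) {
    if (i > n) return(TRUE)
    for (j in which(!used)) {
      if (g1$elements[i] == g2$elements[j] && d1[i] == d2[j]) {
        ok <- TRUE
        for (k in seq_len(i - 1L)) {
          if (A1[i, k] != A2[j, map[k]]) { ok <- FALSE; break }
        }
        if (ok) {
          map[i] <<- j; used[j] <<- TRUE
          if (bt(i + 1L)) return(TRUE)
          used[j] <<- FALSE; map[i] <<- NA_integer_
        }
      }
    }
    FALSE
  }
  bt(1L)
}

# all automorphisms of an element-labeled graph, as a list of permutations
all_automorphisms <- function(g) {
  n <- length(g$elements)
  d <- atom_degrees(g)
  A <- adjacency_matrix(g)
  map <- rep(NA_integer_, n); used <- logical(n)
  found <- list()
  bt <- function(i) {
    if (i > n) {
      found[[length(found) + 1L]] <<- map
      return(invisible(NULL))
    }
    for (j in which(!used)) {
      if (g$elements[i] == g$elements[j] && d[i] == d[j]) {
        ok <- TRUE
        for (k in seq_len(i - 1L)) {
          if (A[i, k] != A[j, map[k]]) { ok <- FALSE; break }
        }
        if (ok) {
          map[i] <<- j; used[j] <<- TRUE
          bt(i + 1L)
          used[j] <<- FALSE; map[i] <<- NA_integer_
        }
      }
    }
  }
  bt(1L)
  found
}

# number of orbits of the given sites under the automorphism group
orbit_count <- function(g, sites) {
  auts <- all_automorphisms(g)
  reps <- vapply(sites, function(s) {
    min(vapply(auts, function(a) a[s], integer(1)))
  }, integer(1))
  length(unique(reps))
}

# cycle sizes by edge deletion + shortest path (independent of the
# package's simple-cycle DFS); returns sorted unique cycle vertex sets
oracle_cycle_lengths <- function(g) {
  n <- length(g$elements)
  ig <- igraph::make_graph(edges = as.vector(t(g$bonds)), n = n,
                           directed = FALSE)
  seen <- character(0)
  lens <- integer(0)
  for (k in seq_len(nrow(g$bonds))) {
    ig2 <- igraph::delete_edges(ig, k)
    sp <- suppressWarnings(igraph::shortest_paths(
      ig2, from = g$bonds[k, 1], to = g$bonds[k, 2]))$vpath[[1]]
    if (length(sp) == 0L) next
    verts <- sort(as.integer(sp))
    id <- paste(verts, collapse = ",")
    if (!(id %in% seen)) {
      seen <- c(seen, id)
      lens <- c(lens, length(verts))
    }
  }
  sort(lens)
}

oracle_sssr <- function(g) {
  rank <- nrow(g$bonds) - length(g$elements) + 1L
  sort(oracle_cycle_lengths(g))[seq_len(rank)]
}

# apply a random relabeling of atom indices
relabel <- function(g, perm) {
  elements <- character(length(g$elements))
  elements[perm] <- g$elements
  molgraph(elements, matrix(perm[g$bonds], ncol = 2))
}

# independent constructions (not via the package's skeleton builders)
fixture_bicyclo <- function(x, y, z) {
  bonds <- matrix(integer(0), ncol = 2)
  nxt <- 3L
  for (len in c(x, y, z)) {
    if (len == 0L) {
      bonds <- rbind(bonds, c(1L, 2L))
    } else {
      path <- nxt:(nxt + len - 1L)
      nxt <- nxt + len
      chain <- cbind(c(1L, path), c(path, 2L))
      bonds <- rbind(bonds, chain)
    }
  }
  molgraph(rep("C", 2L + x + y + z), bonds)
}

.ring7 <- function() molgraph(rep("C", 7), cbind(1:7, c(2:7, 1)))
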