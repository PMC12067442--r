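# Molecular graphs for saturated, uncharged C/N compounds.
# Hydrogens are always implicit: H(atom) = valence(element) - heavy degree,
# with valence(C) = 4 and valence(N) = 3. All bonds are single.

.VALENCE <- c(C = 4L, N = 3L)

# IUPAC standard average atomic weights, 3 decimals
.ATOMIC_WEIGHT <- c(C = 12.011, H = 1.008, N = 14.007)

#' Construct a molecular graph
#'
#' A molecular graph is the heavy-atom skeleton of a saturated, uncharged
#' amine: an indexed list of elements (carbon or nitrogen) plus a set of
#' single bonds. Hydrogens are implicit and derived from the free valence of
#' each atom.
#'
#' @param elements Character vector of atom elements, each `"C"` or `"N"`.
#' @param bonds Two-column integer matrix of atom index pairs (one row per
#'   bond), or an empty matrix for a single atom.
#' @return An object of class `molgraph` with components `elements` and
#'   `bonds` (normalized so that the smaller index comes first and rows are
#'   sorted).
#' @examples
#' ring <- molgraph(rep("C", 6), cbind(1:6, c(2:6, 1)))
#' mol_formula(ring)$string  # cyclohexane, "C6H12"
#' @export
molgraph <- function(elements, bonds) {
  elements <- as.character(elements)
  if (length(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 2)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  g <- structure(list(elements = elements, bonds = .normalize_bonds(bonds)),
                 class = "molgraph")
  validate_molgraph(g)
  g
}

.normalize_bonds <- function(bonds) {
  if (nrow(bonds) == 0L) return(bonds)
  b <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  b[order(b[, 1], b[, 2]), , drop = FALSE]
}

#' Validate a molecular graph
#'
#' Checks the structural invariants: elements restricted to C and N, no
#' self-bonds, no parallel bonds, connectivity, and heavy degree within the
#' element's valence (so every implicit-hydrogen count is non-negative).
#'
#' @param g A `molgraph`.
#' @return `g`, invisibly; otherwise an error describing the first violation.
#' @export
validate_molgraph <- function(g) {
  n <- length(g$elements)
  if (n < 1L) stop("molecular graph must contain at least one atom")
  if (!all(g$elements %in% names(.VALENCE))) {
    stop("unsupported element(s): ",
         paste(setdiff(unique(g$elements), names(.VALENCE)), collapse = ", "))
  }
  b <- g$bonds
  if (nrow(b) > 0L) {
    if (any(b < 1L) || any(b > n)) stop("bond references atom index out of range")
    if (any(b[, 1] == b[, 2])) stop("self-bonds are not allowed")
    if (anyDuplicated(b)) stop("parallel bonds are not allowed")
  }
  deg <- atom_degrees(g)
  over <- which(deg > .VALENCE[g$elements])
  if (length(over) > 0L) {
    stop("heavy degree exceeds valence at atom(s) ", paste(over, collapse = ", "))
  }
  if (!.is_connected(n, b)) stop("molecular graph must be connected")
  invisible(g)
}

.is_connected <- function(n, bonds) {
  if (n == 1L) return(TRUE)
  if (nrow(bonds) == 0L) return(FALSE)
  adj <- .adjacency(n, bonds)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

#' Heavy-atom degree of every atom
#' @param g A `molgraph`.
#' @return Integer vector of bond counts per atom index.
#' @export
atom_degrees <- function(g) {
  n <- length(g$elements)
  tabulate(c(g$bonds[, 1], g$bonds[, 2]), nbins = n)
}

#' Implicit hydrogen count of every atom
#' @param g A `molgraph`.
#' @return Integer vector: free valence (valence minus heavy degree) per atom.
#' @export
implicit_hydrogens <- function(g) {
  unname(.VALENCE[g$elements]) - atom_degrees(g)
}

.as_igraph <- function(g) {
  igraph::make_graph(edges = as.vector(t(g$bonds)),
                     n = length(g$elements), directed = FALSE)
}

#' Canonical key of a molecular graph
#'
#' Computes a string identifier that is invariant under any relabeling of the
#' atom indices and differs between non-isomorphic element-labeled graphs.
#' The key is the element sequence and sorted edge list of the BLISS
#' canonical form (element used as the vertex color), so two graphs have
#' equal keys exactly when they are isomorphic as C/N-labeled graphs.
#' Stereochemistry is not represented: identity is 2D graph identity.
#'
#' @param g A `molgraph`.
#' @return A single string, e.g. `"CCCCNN:1-2,1-5,..."`.
#' @export
canonical_key <- function(g) {
  validate_molgraph(g)
  n <- length(g$elements)
  colors <- ifelse(g$elements == "N", 2L, 1L)
  if (n == 1L) return(paste0(g$elements, ":"))
  ig <- .as_igraph(g)
  lab <- igraph::canonical_permutation(ig, colors = colors)$labeling
  elems <- g$elements[order(lab)]
  e <- matrix(lab[g$bonds], ncol = 2)
  e <- .normalize_bonds(e)
  paste0(paste(elems, collapse = ""), ":",
         paste(e[, 1], e[, 2], sep = "-", collapse = ","))
}

#' Molecular formula and weight
#'
#' Counts C, N and implicit H and computes the molecular weight from IUPAC
#' standard average atomic weights (C 12.011, H 1.008, N 14.007).
#'
#' @param g A `molgraph`.
#' @return A list with `C`, `H`, `N` counts, `weight` in Da, and a Hill-order
#'   formula `string` (e.g. `"C4H10N2"`).
#' @examples
#' mol_formula(fixture_molecule("piperazine"))$weight  # 86.138
#' @export
mol_formula <- function(g) {
  validate_molgraph(g)
  nC <- sum(g$elements == "C")
  nN <- sum(g$elements == "N")
  nH <- sum(implicit_hydrogens(g))
  w <- nC * .ATOMIC_WEIGHT[["C"]] + nH * .ATOMIC_WEIGHT[["H"]] +
    nN * .ATOMIC_WEIGHT[["N"]]
  fmt <- function(sym, k) {
    if (k == 0L) "" else if (k == 1L) sym else paste0(sym, k)
  }
  list(C = nC, H = nH, N = nN, weight = w,
       string = paste0(fmt("C", nC), fmt("H", nH), fmt("N", nN)))
}

#' Write a molecular graph as SMILES
#'
#' Emits a SMILES string (Daylight dialect restricted to the space this
#' package enumerates: neutral C/N atoms, single bonds, implicit hydrogens,
#' no stereodescriptors). The output round-trips through [parse_smiles()] to
#' an isomorphic graph.
#'
#' @param g A `molgraph`.
#' @return A SMILES string.
#' @export
to_smiles <- function(g) {
  validate_molgraph(g)
  n <- length(g$elements)
  adj <- .adjacency(n, g$bonds)
  visited <- logical(n)
  parent <- rep(NA_integer_, n)
  ring_digit_at <- vector("list", n)   # digits to print at each atom
  next_digit <- 0L
  closed <- new.env(parent = emptyenv())  # "i-j" keys of back edges seen

  # iterative DFS to classify tree vs ring-closure edges and assign digits
  order_visit <- integer(0)
  stack <- 1L
  visited[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_visit <- c(order_visit, v)
    for (w in rev(adj[[v]])) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  # find back edges: bonds not in the spanning tree
  tree <- paste(pmin(parent, seq_len(n)), pmax(parent, seq_len(n)), sep = "-")
  tree <- tree[!is.na(parent)]
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    ek <- paste(i, j, sep = "-")
    if (!(ek %in% tree)) {
      next_digit <- next_digit + 1L
      if (next_digit > 9L) stop("more than 9 concurrent ring closures unsupported")
      ring_digit_at[[i]] <- c(ring_digit_at[[i]], next_digit)
      ring_digit_at[[j]] <- c(ring_digit_at[[j]], next_digit)
    }
  }
  children <- vector("list", n)
  for (w in seq_len(n)) {
    if (!is.na(parent[w])) children[[parent[w]]] <- c(children[[parent[w]]], w)
  }
  # order children by visit order for determinism
  pos <- match(seq_len(n), order_visit)
  emit <- function(v) {
    tok <- paste0(g$elements[v], paste(ring_digit_at[[v]], collapse = ""))
    kids <- children[[v]]
    if (length(kids) > 1L) kids <- kids[order(pos[kids])]
    if (length(kids) == 0L) return(tok)
    parts <- vapply(kids, emit, character(1))
    if (length(parts) > 1L) {
      branch <- paste0("(", parts[-length(parts)], ")", collapse = "")
      paste0(tok, branch, parts[length(parts)])
    } else {
      paste0(tok, parts)
    }
  }
  emit(1L)
}

#' Parse a SMILES string
#'
#' Reads the SMILES subset this package writes: atoms `C` and `N`, single
#' bonds (explicit `-` accepted), branches, and ring-closure digits
#' (including `%nn`). Aromatic atoms, charges, stereodescriptors and other
#' elements are rejected.
#'
#' @param smiles A single SMILES string.
#' @return A `molgraph`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "")[[1]]
  elements <- character(0)
  bonds <- matrix(integer(0), ncol = 2)
  prev_stack <- integer(0)  # branch stack
  prev <- NA_integer_
  open_rings <- list()      # digit -> atom index awaiting closure
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("C", "N")) {
      elements <- c(elements, ch)
      idx <- length(elements)
      if (!is.na(prev)) bonds <- rbind(bonds, c(prev, idx))
      prev <- idx
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("SMILES branch before any atom: ", smiles)
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch == "-") {
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > length(chars)) stop("truncated %nn ring closure: ", smiles)
        digit <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        digit <- ch
        i <- i + 1L
      }
      if (is.na(prev)) stop("ring-closure digit before any atom: ", smiles)
      if (!is.null(open_rings[[digit]])) {
        bonds <- rbind(bonds, c(open_rings[[digit]], prev))
        open_rings[[digit]] <- NULL
      } else {
        open_rings[[digit]] <- prev
      }
    } else {
      stop("unsupported SMILES token '", ch, "' in: ", smiles)
    }
  }
  if (length(open_rings) > 0L) stop("unclosed ring bond(s) in SMILES: ", smiles)
  if (length(prev_stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles)
  molgraph(elements, bonds)
}

# fixture registry: built lazily from constructive definitions
.fixture_builders <- list(
  cyclopentane = function() .ring_molgraph(5L),
  cyclohexane = function() .ring_molgraph(6L),
  piperazine = function() {
    g <- .ring_molgraph(6L); g$elements[c(1L, 4L)] <- "N"; g
  },
  pyrrolidine = function() {
    g <- .ring_molgraph(5L); g$elements[1L] <- "N"; g
  },
  piperidine = function() {
    g <- .ring_molgraph(6L); g$elements[1L] <- "N"; g
  },
  cyclohexylamine = function() {
    molgraph(c(rep("C", 6L), "N"), rbind(cbind(1:6, c(2:6, 1L)), c(1L, 7L)))
  },
  norbornane = function() .bicyclo_molgraph(2L, 2L, 1L),
  decalin = function() .bicyclo_molgraph(4L, 4L, 0L),
  hydrindane = function() .bicyclo_molgraph(4L, 3L, 0L),
  `bicyclo[2.2.2]octane` = function() .bicyclo_molgraph(2L, 2L, 2L),
  dabco = function() {
    g <- .bicyclo_molgraph(2L, 2L, 2L); g$elements[c(1L, 2L)] <- "N"; g
  }
)

.ring_molgraph <- function(n) {
  molgraph(rep("C", n), cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
}

# bicyclo[x.y.z]: bridgeheads are atoms 1 and 2, joined by three bridges of
# x, y, z intermediate atoms (z = 0 means a direct bond: a fused system)
.bicyclo_molgraph <- function(x, y, z) {
  n <- 2L + x + y + z
  bonds <- matrix(integer(0), ncol = 2)
  nxt <- 3L
  for (len in c(x, y, z)) {
    if (len == 0L) {
      bonds <- rbind(bonds, c(1L, 2L))
    } else {
      path <- nxt:(nxt + len - 1L)
      nxt <- nxt + len
      bonds <- rbind(bonds, c(1L, path[1]))
      if (len > 1L) bonds <- rbind(bonds, cbind(path[-len], path[-1]))
      bonds <- rbind(bonds, c(path[len], 2L))
    }
  }
  molgraph(rep("C", n), bonds)
}

#' Named fixture molecules
#'
#' Returns one of a small registry of reference molecules used throughout the
#' tests and documentation: `"piperazine"`, `"pyrrolidine"`, `"piperidine"`,
#' `"cyclohexylamine"`, `"cyclopentane"`, `"cyclohexane"`, `"norbornane"`,
#' `"decalin"`, `"hydrindane"`, `"bicyclo[2.2.2]octane"`, and `"dabco"` (the
#' bicyclo[2.2.2]octane analog with both bridgeheads as nitrogen).
#'
#' @param name Fixture name (see above).
#' @return A `molgraph`.
#' @export
fixture_molecule <- function(name) {
  builder <- .fixture_builders[[name]]
  if (is.null(builder)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_builders), collapse = ", "))
  }
  builder()
}

#' Names of all fixture molecules
#' @return Character vector of fixture names accepted by [fixture_molecule()].
#' @export
fixture_names <- function() names(.fixture_builders)

#' @export
print.molgraph <- function(x, ...) {
  f <- mol_formula(x)
  cat(sprintf("<molgraph> %s (%d heavy atoms, %d bonds, MW %.2f Da)\n",
              f$string, length(x$elements), nrow(x$bonds), f$weight))
  invisible(x)
}
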