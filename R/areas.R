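#' Define a set of discrete biogeographic areas
#'
#' An area set names the discrete areas of the analysis and records which
#' pairs are adjacent. Ranges (subsets of areas) are later restricted to
#' subsets that induce a connected subgraph of the adjacency relation, the
#' usual way "impossible" disjunct ranges are excluded from the DEC state
#' space.
#'
#' @param areas Character vector of single-letter area codes (default the
#'   four-area coding `A` = Indian Subcontinent, `B` = Southeast Asia,
#'   `C` = Philippines, `D` = east of the Wallace Line).
#' @param adjacency Either the string `"full"` (every pair adjacent), or a
#'   two-column character matrix of adjacent pairs.
#' @return An object of class `area_set`: list with `areas` and a symmetric
#'   logical `adjacency` matrix (irreflexive).
#' @examples
#' area_set(c("A", "B"), adjacency = "full")
#' @export
area_set <- function(areas = c("A", "B", "C", "D"), adjacency = "full") {
  areas <- as.character(areas)
  if (length(areas) < 1L) stop("need at least one area")
  if (anyDuplicated(areas)) stop("duplicate area codes")
  n <- length(areas)
  adj <- matrix(FALSE, n, n, dimnames = list(areas, areas))
  if (identical(adjacency, "full")) {
    adj[] <- TRUE
  } else {
    adjacency <- as.matrix(adjacency)
    if (ncol(adjacency) != 2L) stop("adjacency must be a 2-column matrix of pairs")
    for (i in seq_len(nrow(adjacency))) {
      a <- adjacency[i, 1]; b <- adjacency[i, 2]
      if (!(a %in% areas) || !(b %in% areas)) stop("adjacency names unknown area")
      adj[a, b] <- TRUE; adj[b, a] <- TRUE
    }
  }
  diag(adj) <- FALSE
  structure(list(areas = areas, adjacency = adj), class = "area_set")
}

#' Default four-area set with the Indian-Subcontinent adjacency restriction
#'
#' Area `A` (Indian Subcontinent) is adjacent only to `B` (Southeast Asia);
#' `B`, `C` (Philippines) and `D` (east of the Wallace Line) are mutually
#' adjacent. This realizes the restriction that India does not touch the
#' Philippine or trans-Wallacean ranges, so disjunct ranges such as
#' \{A,C\} are excluded.
#'
#' @return An `area_set`.
#' @export
default_area_set <- function() {
  area_set(c("A", "B", "C", "D"),
           adjacency = rbind(c("A", "B"), c("B", "C"), c("B", "D"), c("C", "D")))
}

#' @export
print.area_set <- function(x, ...) {
  cat("Area set:", paste(x$areas, collapse = " "), "\n")
  pairs <- which(x$adjacency & upper.tri(x$adjacency), arr.ind = TRUE)
  cat("Adjacent pairs:",
      paste(x$areas[pairs[, 1]], x$areas[pairs[, 2]], sep = "-", collapse = " "),
      "\n")
  invisible(x)
}

# ---- bitmask helpers (ranges are integer bitmasks over area_set$areas) ----

bit_count <- function(m) vapply(m, function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:30)) != 0L), integer(1))

bits_of <- function(m) which(bitwAnd(m, bitwShiftL(1L, seq_len(31L) - 1L)) != 0L)

mask_of <- function(idx) sum(bitwShiftL(1L, idx - 1L))

# is the subset `m` connected under the adjacency matrix?
mask_connected <- function(m, adj) {
  members <- bits_of(m)
  if (length(members) <= 1L) return(TRUE)
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, function(v) members[adj[v, members]])))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}

#' Convert an area string to a range label and back
#'
#' Ranges are printed as concatenated area codes in area-set order, e.g.
#' `"AB"`.
#' @param mask Integer bitmask.
#' @param aset An `area_set`.
#' @return `range_label`: a string; `range_mask`: an integer bitmask.
#' @keywords internal
range_label <- function(mask, aset) {
  vapply(mask, function(m) {
    if (m == 0L) "0" else paste(aset$areas[bits_of(m)], collapse = "")
  }, character(1))
}

range_mask <- function(label, aset) {
  vapply(label, function(s) {
    if (identical(s, "0") || !nzchar(s)) return(0L)
    ch <- strsplit(s, "")[[1]]
    idx <- match(ch, aset$areas)
    if (anyNA(idx)) stop("unknown area letter in range '", s, "'")
    if (anyDuplicated(idx)) stop("duplicate area letter in range '", s, "'")
    mask_of(idx)
  }, integer(1), USE.NAMES = FALSE)
}

#' Enumerate allowed range states
#'
#' Lists every nonempty, adjacency-connected subset of the areas with at most
#' `max_size` areas, in deterministic order (by size, then bitmask value).
#' These subsets, plus the absorbing null (extinct) range, form the DEC state
#' space.
#'
#' @param aset An `area_set`.
#' @param max_size Optional cap on range size (`NULL` = no cap).
#' @return Character vector of range labels; integer bitmasks in attribute
#'   `"mask"`.
#' @examples
#' length(enumerate_ranges(area_set(c("A", "B", "C", "D"), "full")))  # 15
#' length(enumerate_ranges(default_area_set()))                       # 12
#' @export
enumerate_ranges <- function(aset, max_size = NULL) {
  stopifnot(inherits(aset, "area_set"))
  n <- length(aset$areas)
  if (n < 1L) stop("empty area list")
  if (is.null(max_size)) max_size <- n
  masks <- seq_len(2L^n - 1L)
  sz <- bit_count(masks)
  keep <- sz <= max_size &
    vapply(masks, mask_connected, logical(1), adj = aset$adjacency)
  masks <- masks[keep]
  masks <- masks[order(bit_count(masks), masks)]
  structure(range_label(masks, aset), mask = masks)
}

# ---- DEC state space: ranges + null state, cladogenesis table ----

# Precomputes everything the pruning algorithm needs: the ordered state list
# (allowed ranges then the null state last), gain/loss transition templates,
# and the flattened cladogenesis outcome table.
dec_state_space <- function(aset = default_area_set(), max_range_size = NULL) {
  labels <- enumerate_ranges(aset, max_range_size)
  masks <- attr(labels, "mask")
  K <- length(masks)
  idx_of <- integer(2L^length(aset$areas))  # mask -> state index, 0 if disallowed
  idx_of[masks] <- seq_len(K)
  null_idx <- K + 1L

  # cladogenesis outcomes, flattened: parent state, left state, right state, weight
  po <- li <- ri <- integer(0)
  w <- numeric(0)
  for (k in seq_len(K)) {
    m <- masks[k]
    members <- bits_of(m)
    if (length(members) == 1L) {
      out <- cbind(k, k)
    } else {
      out <- NULL
      # peripheral isolate: ({a}, R) and (R, {a})
      for (a in members) {
        s <- idx_of[mask_of(a)]
        out <- rbind(out, c(s, k), c(k, s))
      }
      # vicariance with a singleton part: (S, R \ S), |S| = 1 or |R \ S| = 1;
      # the swapped order is added only when the complement is widespread,
      # otherwise it arises from the other member's iteration
      for (a in members) {
        s1 <- mask_of(a); s2 <- m - s1
        i1 <- idx_of[s1]; i2 <- idx_of[s2]
        if (i1 > 0L && i2 > 0L) {
          out <- rbind(out, c(i1, i2))
          if (length(members) > 2L) out <- rbind(out, c(i2, i1))
        }
      }
    }
    nk <- nrow(out)
    po <- c(po, rep.int(k, nk)); li <- c(li, out[, 1]); ri <- c(ri, out[, 2])
    w <- c(w, rep.int(1 / nk, nk))
  }

  structure(list(aset = aset, labels = labels, masks = masks, K = K,
                 null_idx = null_idx, n_states = K + 1L, idx_of = idx_of,
                 clado = list(parent = po, left = li, right = ri, weight = w)),
            class = "dec_state_space")
}

#' Cladogenesis outcomes of an ancestral range
#'
#' At a node, a single-area range is inherited identically by both daughters.
#' A widespread range `R` splits either by peripheral-isolate (subset)
#' sympatry -- one daughter inherits a single area of `R`, the other inherits
#' all of `R` -- or by vicariance into two disjoint parts one of which is a
#' single area (both parts must themselves be allowed ranges). Outcomes are
#' ordered (left/right distinct) and equally weighted, weights summing to 1.
#'
#' @param range Range label, e.g. `"AB"`.
#' @param aset An `area_set`.
#' @param max_range_size Optional state-space cap (as in [enumerate_ranges()]).
#' @return Data frame with columns `left`, `right`, `weight`.
#' @examples
#' cladogenesis_outcomes("AB", area_set(c("A", "B"), "full"))  # 6 outcomes
#' @export
cladogenesis_outcomes <- function(range, aset = default_area_set(),
                                  max_range_size = NULL) {
  sp <- dec_state_space(aset, max_range_size)
  m <- range_mask(range, sp$aset)
  if (m == 0L) stop("null range has no cladogenesis outcomes")
  k <- sp$idx_of[m]
  if (k == 0L) stop("range '", range, "' is not an allowed state")
  sel <- sp$clado$parent == k
  data.frame(left = sp$labels[sp$clado$left[sel]],
             right = sp$labels[sp$clado$right[sel]],
             weight = sp$clado$weight[sel],
             stringsAsFactors = FALSE)
}
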