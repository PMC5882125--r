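#' Periodic cell lattices with explicit apoplast edges
#'
#' Build the periodic lattices on which all models run: a one-dimensional
#' ring of `N` cells or a two-dimensional torus of hexagonal cells. Each
#' cell-cell interface carries one apoplast compartment ("edge"); directed
#' PIN1 densities are indexed by (cell, neighbor slot), so every undirected
#' edge flanks two directed PIN1 values.
#'
#' @details
#' `ring_lattice(N)` gives cell `i` the neighbors `i - 1` and `i + 1`
#' (mod `N`, 1-based ids) and numbers the edge between `i` and `i + 1` as
#' `i` (edge `N` closes the ring). Apoplast-edge adjacency (used by the
#' apoplast-diffusion model variants) is defined on the ring only: edge `e`
#' neighbors edges `e - 1` and `e + 1` (mod `N`).
#'
#' `hex_lattice(nx, ny)` uses axial (rhombic) coordinates on a torus: cell
#' `(u, v)` neighbors `(u±1, v)`, `(u, v±1)`, `(u+1, v-1)` and `(u-1, v+1)`,
#' all modulo `(nx, ny)`, so every cell has exactly 6 distinct neighbors
#' (this requires `nx, ny >= 3`) and there are `3 * nx * ny` edges.
#'
#' @param N number of cells in the ring; must be at least 3 (with 2 cells
#'   the two interfaces between the same cell pair would collapse).
#' @param nx,ny torus dimensions; both at least 3.
#' @return An object of class `"auxin_lattice"`: a list with elements
#'   `n_cells`, `K` (neighbors per cell), `type` (`"ring"` or `"hex"`),
#'   `nb` (`n_cells x K` integer matrix of neighbor ids), `n_edges`,
#'   `edge_cells` (`n_edges x 2` matrix of flanking cells), `edge_slot`
#'   (`n_cells x K` matrix: edge id seen from (cell, slot)), `opp`
#'   (`n_cells x K` matrix of linear indices into an `n_cells x K` array
#'   giving the reverse directed slot), `edge_dir1`/`edge_dir2` (linear
#'   directed-slot indices of the two sides of each edge), and for rings
#'   `edge_adj` (`n_edges x 2` neighboring edge ids).
#' @examples
#' lat <- ring_lattice(6)
#' lat$nb[1, ]      # neighbors of cell 1: 6 and 2
#' hex <- hex_lattice(3, 3)
#' hex$n_edges      # 27
#' @export
ring_lattice <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 3L)
    stop("invalid lattice: a ring needs N >= 3 cells (N = ", N, ")")
  idx <- seq_len(N)
  left  <- ifelse(idx == 1L, N, idx - 1L)
  right <- ifelse(idx == N, 1L, idx + 1L)
  nb <- cbind(left, right, deparse.level = 0)
  # edge i joins cells i and i+1 (edge N joins N and 1)
  edge_cells <- cbind(idx, right, deparse.level = 0)
  edge_slot <- cbind(left, idx, deparse.level = 0)  # slot 1 looks left -> edge i-1
  lat <- list(
    n_cells = N, K = 2L, type = "ring",
    nb = nb, n_edges = N, edge_cells = edge_cells, edge_slot = edge_slot,
    edge_adj = cbind(left, right, deparse.level = 0)
  )
  finish_lattice(lat)
}

#' @rdname ring_lattice
#' @export
hex_lattice <- function(nx, ny) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (any(is.na(c(nx, ny))) || nx < 3L || ny < 3L)
    stop("invalid lattice: hexagonal torus needs nx, ny >= 3 (got ",
         nx, " x ", ny, ")")
  n <- nx * ny
  id <- function(u, v) (u %% nx) + nx * (v %% ny) + 1L
  uu <- rep(0:(nx - 1L), times = ny)
  vv <- rep(0:(ny - 1L), each = nx)
  # neighbor slots 1..6: (+1,0), (0,+1), (+1,-1), (-1,0), (0,-1), (-1,+1)
  nb <- cbind(id(uu + 1L, vv),      id(uu, vv + 1L), id(uu + 1L, vv - 1L),
              id(uu - 1L, vv),      id(uu, vv - 1L), id(uu - 1L, vv + 1L))
  # one edge per cell for each of the three canonical directions (slots 1:3)
  n_edges <- 3L * n
  edge_id <- function(cell, dir) 3L * (cell - 1L) + dir
  edge_slot <- matrix(0L, n, 6L)
  for (d in 1:3) edge_slot[, d] <- edge_id(seq_len(n), d)
  # reverse slots: slot d+3 of cell i sees the canonical edge of neighbor
  for (d in 4:6) edge_slot[, d] <- edge_id(nb[, d], d - 3L)
  edge_cells <- matrix(0L, n_edges, 2L)
  for (d in 1:3) {
    e <- edge_id(seq_len(n), d)
    edge_cells[e, 1L] <- seq_len(n)
    edge_cells[e, 2L] <- nb[, d]
  }
  lat <- list(
    n_cells = n, K = 6L, type = "hex", nx = nx, ny = ny,
    nb = nb, n_edges = n_edges, edge_cells = edge_cells,
    edge_slot = edge_slot, edge_adj = NULL
  )
  finish_lattice(lat)
}

# Shared wiring: reverse-slot linear indices and per-edge directed slots.
finish_lattice <- function(lat) {
  n <- lat$n_cells; K <- lat$K; nb <- lat$nb
  opp <- matrix(0L, n, K)
  for (s in seq_len(K)) {
    j <- nb[, s]
    # slot s2 of j such that nb[j, s2] == i
    found <- rep(0L, n)
    for (s2 in seq_len(K)) {
      hit <- nb[j, s2] == seq_len(n) & found == 0L
      found[hit] <- s2
    }
    if (any(found == 0L)) stop("internal error: asymmetric adjacency")
    opp[, s] <- (found - 1L) * n + j
  }
  # stored dimension-less (column-major over n x K) so that indexing a
  # directed n x K matrix by it stays plain linear indexing
  lat$opp <- as.integer(opp)
  dir1 <- integer(lat$n_edges); dir2 <- integer(lat$n_edges)
  seen <- logical(lat$n_edges)
  for (s in seq_len(K)) {
    e <- lat$edge_slot[, s]
    lin <- (s - 1L) * n + seq_len(n)
    first <- !seen[e]
    dir1[e[first]] <- lin[first]
    dir2[e[!first]] <- lin[!first]
    seen[e] <- TRUE
  }
  if (!all(seen)) stop("internal error: orphan edge")
  lat$edge_dir1 <- dir1; lat$edge_dir2 <- dir2
  class(lat) <- "auxin_lattice"
  lat
}

#' Look up the apoplast edge between two adjacent cells
#'
#' @param lattice an [ring_lattice()] / [hex_lattice()] object.
#' @param i,j adjacent cell ids.
#' @return integer edge id; symmetric in `i`, `j`.
#' @export
edge_of <- function(lattice, i, j) {
  s <- match(j, lattice$nb[i, ])
  if (is.na(s)) stop("cells ", i, " and ", j, " are not adjacent")
  lattice$edge_slot[i, s]
}

#' @export
print.auxin_lattice <- function(x, ...) {
  cat(sprintf("auxin lattice: %s, %d cells (K = %d), %d apoplast edges\n",
              if (x$type == "hex") sprintf("%d x %d hex torus", x$nx, x$ny)
              else "1D ring", x$n_cells, x$K, x$n_edges))
  invisible(x)
}

#' Serialize a lattice to JSON
#'
#' Writes cells, neighbor lists and the edge list in a plain JSON form,
#' mainly for debugging and external fixtures.
#'
#' @param lattice an `auxin_lattice`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
lattice_to_json <- function(lattice, path = NULL) {
  obj <- list(
    type = lattice$type, n_cells = lattice$n_cells, K = lattice$K,
    neighbors = unname(apply(lattice$nb, 1L, as.integer, simplify = FALSE)),
    edges = unname(apply(lattice$edge_cells, 1L, as.integer, simplify = FALSE))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}
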