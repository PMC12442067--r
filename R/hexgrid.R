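# Axial hexagon lattice primitives.
#
# Rings live on an axial coordinate grid (q, r); the 6 lattice directions are
# indexed 0..5 at multiples of 60 degrees.  Carbon positions use a doubled
# integer grid in which a ring centred at axial (q, r) sits at
# (x, y) = (2q + r, 3r) and its six vertices are center + VERTEX_OFF[k, ].
# All vertex coordinates are integers, so shared corners coincide exactly.

# direction d (0-based) -> axial step
DIR_Q <- c(1L, 0L, -1L, -1L, 0L, 1L)
DIR_R <- c(0L, 1L, 1L, 0L, -1L, -1L)

# vertex offsets v0..v5 on the doubled grid (row k+1 = v_k)
VERTEX_OFF <- matrix(c(1L, 1L,
                       0L, 2L,
                       -1L, 1L,
                       -1L, -1L,
                       0L, -2L,
                       1L, -1L), ncol = 2, byrow = TRUE)

# the hexagon edge facing direction d joins vertices v_d and v_{d-1}
edge_slots <- function(d) c(d, (d + 5L) %% 6L)

opp_dir <- function(d) (d + 3L) %% 6L

# 60-degree counter-clockwise rotation in axial coordinates
rot60_axial <- function(q, r) cbind(-r, q + r)

# reflection across the q axis (an involution of the lattice)
reflect_axial <- function(q, r) cbind(q + r, -r)

# direction images under the 12 lattice symmetries
dir_rotate <- function(d, k) (d + k) %% 6L
dir_reflect <- function(d) (6L - d) %% 6L

axial_neighbors <- function(q, r) cbind(q + DIR_Q, r + DIR_R)

# direction from cell (q1,r1) to adjacent cell (q2,r2), or NA
axial_direction <- function(q1, r1, q2, r2) {
  hit <- which(DIR_Q == (q2 - q1) & DIR_R == (r2 - r1))
  if (length(hit) == 0L) NA_integer_ else hit - 1L
}
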