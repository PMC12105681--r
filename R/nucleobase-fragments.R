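# Idealized nucleobase and backbone fragment geometries, built in code from
# standard bond lengths: aromatic ring bonds ~1.39 A (pyrimidine) / 1.37 A
# (imidazole), exocyclic C=O 1.23 A, exocyclic C-N 1.34 A, methyl C-C 1.50 A,
# sugar C-C 1.53 A, C-O 1.43 A, P-O 1.48/1.60 A. Planar bases; a rough 3D
# sugar-phosphate unit. These are distance-distribution stand-ins, not
# crystallographic geometries.

.regular_ring <- function(n, bond) {
  R <- bond / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(R * cos(ang), R * sin(ang), 0)
}

# Regular n2-gon sharing the edge (p1, p2), built on the side of the origin
# away from the first ring's centre.
.fused_ring <- function(p1, p2, n2, away_from = c(0, 0, 0)) {
  e <- sqrt(sum((p2 - p1)^2))
  mid <- (p1 + p2) / 2
  ap <- e / (2 * tan(pi / n2))
  edge_dir <- (p2 - p1) / e
  normal <- c(-edge_dir[2], edge_dir[1], 0)
  if (sum((mid + ap * normal - away_from[1:3])^2) <
      sum((mid - ap * normal - away_from[1:3])^2)) {
    normal <- -normal
  }
  centre <- mid + ap * normal
  a1 <- atan2(p1[2] - centre[2], p1[1] - centre[1])
  a2 <- atan2(p2[2] - centre[2], p2[1] - centre[1])
  step <- 2 * pi / n2
  dirn <- if (sin(a2 - a1) > 0) 1 else -1
  R <- sqrt(sum((p1 - centre)^2))
  ang <- a1 + dirn * step * seq(2, n2 - 1)
  cbind(centre[1] + R * cos(ang), centre[2] + R * sin(ang), 0)
}

# Exocyclic substituent: bonded to ring atom `at`, pointing radially away
# from the ring centroid.
.exocyclic <- function(ring, at, bond) {
  centroid <- colMeans(ring)
  u <- ring[at, ] - centroid
  u <- u / sqrt(sum(u^2))
  ring[at, ] + bond * u
}

.pyrimidine_fragment <- function(kind) {
  ring <- .regular_ring(6, 1.39)                  # N1 C2 N3 C4 C5 C6
  elem <- c("N", "C", "N", "C", "C", "C")
  xyz <- ring
  if (kind == "C") {                              # cytosine: O2, N4
    xyz <- rbind(xyz, .exocyclic(ring, 2, 1.23), .exocyclic(ring, 4, 1.34))
    elem <- c(elem, "O", "N")
  } else {                                        # thymine: O2, O4, C5-methyl
    xyz <- rbind(xyz, .exocyclic(ring, 2, 1.23), .exocyclic(ring, 4, 1.23),
                 .exocyclic(ring, 5, 1.50))
    elem <- c(elem, "O", "O", "C")
  }
  list(xyz = xyz, elem = elem)
}

.purine_fragment <- function(kind) {
  hex <- .regular_ring(6, 1.39)                   # N1 C2 N3 C4 C5 C6
  elem <- c("N", "C", "N", "C", "C", "C")
  imid <- .fused_ring(hex[4, ], hex[5, ], 5)      # N7 C8 N9 on C4-C5 edge
  xyz <- rbind(hex, imid)
  elem <- c(elem, "N", "C", "N")
  if (kind == "A") {                              # adenine: N6
    xyz <- rbind(xyz, .exocyclic(hex, 6, 1.34))
    elem <- c(elem, "N")
  } else {                                        # guanine: O6, N2
    xyz <- rbind(xyz, .exocyclic(hex, 6, 1.23), .exocyclic(hex, 2, 1.34))
    elem <- c(elem, "O", "N")
  }
  list(xyz = xyz, elem = elem)
}

.backbone_fragment <- function() {
  # furanose ring (C1' C2' C3' C4' O4'), C5' exocyclic, then O5'-P with two
  # non-bridging O and O3' bridging back; torsions flattened.
  ring <- .regular_ring(5, 1.45)
  elem <- c("C", "C", "C", "C", "O")
  c5 <- .exocyclic(ring, 4, 1.53)
  o5 <- c5 + c(0, 0, 1.43)
  p <- o5 + c(1.30, 0, 0.93)                      # |P-O5'| = 1.60
  op1 <- p + c(0.6, 1.20, 0.60)                   # ~1.48
  op2 <- p + c(0.6, -1.20, 0.60)
  o3 <- .exocyclic(ring, 3, 1.43)
  xyz <- rbind(ring, c5, o5, p, op1, op2, o3)
  elem <- c(elem, "C", "O", "P", "O", "O", "O")
  list(xyz = xyz, elem = elem)
}

#' Idealized nucleobase / backbone fragment
#'
#' Returns a small [cluster_model()] with an idealized geometry for one
#' nucleobase (purine or pyrimidine ring plus exocyclic substituents) or the
#' generic sugar-phosphate backbone unit, built from standard bond lengths.
#' Used by [nucleobase_model()] to reproduce the sharp low-r structure of
#' aqueous DNA as a base-ratio linear combination.
#'
#' @param kind One of `"A"`, `"C"`, `"G"`, `"T"`, `"backbone"`.
#' @return A [cluster_model()] (biso 0; set before use).
#' @export
nucleobase_fragment <- function(kind) {
  frag <- switch(kind,
                 A = .purine_fragment("A"),
                 G = .purine_fragment("G"),
                 C = .pyrimidine_fragment("C"),
                 T = .pyrimidine_fragment("T"),
                 backbone = .backbone_fragment(),
                 abort(paste0("Unknown fragment kind: ", kind),
                       class = "clusterpdf_validation_error"))
  cluster_model(tibble(element = frag$elem,
                       x = frag$xyz[, 1], y = frag$xyz[, 2], z = frag$xyz[, 3]),
                name = paste0("fragment ", kind))
}
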