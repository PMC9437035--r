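# Grantham (1974) amino-acid physicochemical properties and distances.
# Properties: composition c (atomic weight ratio of hetero elements),
# polarity p, molecular volume v. Distance:
#   D(a, b) = rho * sqrt(alpha (c_a-c_b)^2 + beta (p_a-p_b)^2 + gamma (v_a-v_b)^2)
# with alpha = 1.833, beta = 0.1018, gamma = 0.000399 and rho = 50.723
# scaling the mean over the 190 residue pairs to 100. Distances are served
# from the published integer table, whose printed values round-trip with the
# formula for 187/190 pairs (three entries differ by printing-era rounding).

.grantham_aa <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                  "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

.grantham_props <- data.frame(
  residue = .grantham_aa,
  composition = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
                  0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
  polarity = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
               6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  volume = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
             136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE)

.grantham_constants <- c(alpha = 1.833, beta = 0.1018, gamma = 0.000399,
                         rho = 50.723)

# Published pairwise distances (upper triangle in the row order above).
.grantham_published <- list(
  S = c(R = 110, L = 145, P = 74, T = 58, A = 99, V = 124, G = 56, I = 142,
        F = 155, Y = 144, C = 112, H = 89, Q = 68, N = 46, K = 121, D = 65,
        E = 80, M = 135, W = 177),
  R = c(L = 102, P = 103, T = 71, A = 112, V = 96, G = 125, I = 97, F = 97,
        Y = 77, C = 180, H = 29, Q = 43, N = 86, K = 26, D = 96, E = 54,
        M = 91, W = 101),
  L = c(P = 98, T = 92, A = 96, V = 32, G = 138, I = 5, F = 22, Y = 36,
        C = 198, H = 99, Q = 113, N = 153, K = 107, D = 172, E = 138,
        M = 15, W = 61),
  P = c(T = 38, A = 27, V = 68, G = 42, I = 95, F = 114, Y = 110, C = 169,
        H = 77, Q = 76, N = 91, K = 103, D = 108, E = 93, M = 87, W = 147),
  T = c(A = 58, V = 69, G = 59, I = 89, F = 103, Y = 92, C = 149, H = 47,
        Q = 42, N = 65, K = 78, D = 85, E = 65, M = 81, W = 128),
  A = c(V = 64, G = 60, I = 94, F = 113, Y = 112, C = 195, H = 86, Q = 91,
        N = 111, K = 106, D = 126, E = 107, M = 84, W = 148),
  V = c(G = 109, I = 29, F = 50, Y = 55, C = 192, H = 84, Q = 96, N = 133,
        K = 97, D = 152, E = 121, M = 21, W = 88),
  G = c(I = 135, F = 153, Y = 147, C = 159, H = 98, Q = 87, N = 80, K = 127,
        D = 94, E = 98, M = 127, W = 184),
  I = c(F = 21, Y = 33, C = 198, H = 94, Q = 109, N = 149, K = 102, D = 168,
        E = 134, M = 10, W = 61),
  F = c(Y = 22, C = 205, H = 100, Q = 116, N = 158, K = 102, D = 177,
        E = 140, M = 28, W = 40),
  Y = c(C = 194, H = 83, Q = 99, N = 143, K = 85, D = 160, E = 122, M = 36,
        W = 37),
  C = c(H = 174, Q = 154, N = 139, K = 202, D = 154, E = 170, M = 196,
        W = 215),
  H = c(Q = 24, N = 68, K = 32, D = 81, E = 40, M = 87, W = 115),
  Q = c(N = 46, K = 53, D = 61, E = 29, M = 101, W = 130),
  N = c(K = 94, D = 23, E = 42, M = 142, W = 174),
  K = c(D = 101, E = 56, M = 95, W = 110),
  D = c(E = 45, M = 160, W = 181),
  E = c(M = 126, W = 152),
  M = c(W = 67))

.grantham_matrix_build <- function() {
  m <- matrix(0, 20, 20, dimnames = list(.grantham_aa, .grantham_aa))
  for (a in names(.grantham_published)) {
    for (b in names(.grantham_published[[a]])) {
      m[a, b] <- m[b, a] <- .grantham_published[[a]][[b]]
    }
  }
  m
}

.grantham_matrix <- .grantham_matrix_build()

# Continuous formula value (used by the round-trip unit test).
grantham_formula <- function(a, b) {
  k <- .grantham_constants
  pa <- .grantham_props[match(a, .grantham_props$residue), ]
  pb <- .grantham_props[match(b, .grantham_props$residue), ]
  unname(k["rho"] * sqrt(k["alpha"] * (pa$composition - pb$composition)^2 +
                           k["beta"] * (pa$polarity - pb$polarity)^2 +
                           k["gamma"] * (pa$volume - pb$volume)^2))
}

#' Grantham physicochemical table
#'
#' @return list with `properties` (data frame of per-residue composition,
#'   polarity and volume; also available as named vectors under
#'   `$properties$composition` etc. keyed by residue), `matrix` (the 20 x 20
#'   published integer distance matrix) and `constants` (alpha, beta, gamma,
#'   rho of the distance formula).
#' @export
grantham_table <- function() {
  props <- list(
    composition = stats::setNames(.grantham_props$composition, .grantham_aa),
    polarity = stats::setNames(.grantham_props$polarity, .grantham_aa),
    volume = stats::setNames(.grantham_props$volume, .grantham_aa))
  list(properties = props, matrix = .grantham_matrix,
       constants = .grantham_constants)
}

#' Grantham distance between amino-acid residues
#'
#' Physicochemical dissimilarity combining composition, polarity and
#' molecular volume; symmetric, zero on identity, maximum 215 (Trp-Cys).
#' Vectorized over residue pairs.
#'
#' @param res_a,res_b single-letter residue codes.
#' @return numeric distances.
#' @examples
#' grantham_distance("L", "I")  # 5
#' grantham_distance("W", "C")  # 215
#' @export
grantham_distance <- function(res_a, res_b) {
  res_a <- toupper(res_a); res_b <- toupper(res_b)
  bad <- !(res_a %in% .grantham_aa) | !(res_b %in% .grantham_aa)
  if (any(bad)) {
    stopf("gap or unknown residue in Grantham distance: %s",
          paste(unique(c(res_a[bad], res_b[bad])), collapse = ", "))
  }
  .grantham_matrix[cbind(res_a, res_b)]
}
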