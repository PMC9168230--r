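# Closed-form validation oracle for the forward solver: the potential of
# antipodal point-current electrodes on a set of concentric conductive
# shells, expressed as a Legendre series.  Per harmonic degree n the
# radial part in shell j is A_j r^n + B_j r^-(n+1); continuity of phi and
# of the radial current density sigma dphi/dr across interfaces plus the
# surface current condition determine the coefficients.  The radial basis
# is rescaled per shell to stay in [0, 1], keeping the series stable to
# hundreds of terms.

#' Analytic concentric-shell potential evaluator
#'
#' Returns an evaluator for the potential (volts) inside concentric
#' conductive shells driven by a point current source at
#' `+electrode_axis * radii[1]` and sink at the antipode, each carrying
#' `injected_current`.  Serves as the independent oracle for the
#' finite-element solver; with a single shell it reduces to the classical
#' homogeneous-sphere series.
#'
#' @param radii_mm Strictly decreasing outer shell radii in mm (outermost
#'   first); shell `j` occupies `[radii[j+1], radii[j]]`.
#' @param sigmas Conductivities (S/m), one per shell, outermost first.
#' @param electrode_axis Unit vector from the centre to the source
#'   electrode.
#' @param injected_current Current in amperes.
#' @param n_terms Series truncation order (harmonics 1..n_terms).
#' @return Function mapping an N x 3 matrix of positions (mm, inside the
#'   outer radius) to potentials (V).
#' @export
analytic_shell_potential <- function(radii_mm, sigmas,
                                     electrode_axis = c(0, 0, 1),
                                     injected_current = 2e-3,
                                     n_terms = 100) {
  if (any(diff(radii_mm) >= 0)) stop("radii must be strictly decreasing")
  if (length(sigmas) != length(radii_mm)) stop("one conductivity per shell")
  if (any(sigmas <= 0)) stop("conductivities must be positive")
  if (n_terms < 1) stop("n_terms must be >= 1")
  axis <- electrode_axis / sqrt(sum(electrode_axis^2))
  R <- radii_mm * 1e-3                      # metres
  m <- length(R)
  Rin <- c(R[-1], 0)                        # inner radius of each shell
  # Acoef[j, n], Bcoef[j, n]: coefficients of the scaled basis
  # (r/R_j)^n and (Rin_j/r)^(n+1) in shell j (B of innermost is 0).
  Acoef <- matrix(0, m, n_terms); Bcoef <- matrix(0, m, n_terms)
  nunk <- 2 * m - 1
  for (n in seq_len(n_terms)) {
    M <- matrix(0, nunk, nunk); rhs <- numeric(nunk)
    aix <- function(j) 2 * j - 1            # index of A_j
    bix <- function(j) 2 * j                # index of B_j (j < m)
    # outer surface: sigma_1 dphi/dr (R1) = I (2n+1) / (4 pi R1^2)
    M[1, aix(1)] <- sigmas[1] * n / R[1]
    if (m > 1) M[1, bix(1)] <- -sigmas[1] * (n + 1) / R[1] * (Rin[1] / R[1])^(n + 1)
    rhs[1] <- injected_current * (2 * n + 1) / (4 * pi * R[1]^2)
    if (m > 1) {
      for (j in seq_len(m - 1)) {
        r <- Rin[j]                         # interface between shell j and j+1
        row_c <- 2 * j                      # potential continuity
        row_f <- 2 * j + 1                  # flux continuity
        M[row_c, aix(j)] <- (r / R[j])^n
        M[row_c, bix(j)] <- 1               # (Rin_j / r)^(n+1) = 1 at r = Rin_j
        M[row_f, aix(j)] <- sigmas[j] * n / R[j] * (r / R[j])^(n - 1)
        M[row_f, bix(j)] <- -sigmas[j] * (n + 1) / r
        M[row_c, aix(j + 1)] <- -(r / R[j + 1])^n
        M[row_f, aix(j + 1)] <- -sigmas[j + 1] * n / R[j + 1] * (r / R[j + 1])^(n - 1)
        if (j + 1 < m) {
          M[row_c, bix(j + 1)] <- -(Rin[j + 1] / r)^(n + 1)
          M[row_f, bix(j + 1)] <- sigmas[j + 1] * (n + 1) / r * (Rin[j + 1] / r)^(n + 1)
        }
      }
    }
    sol <- solve(M, rhs)
    Acoef[, n] <- sol[aix(seq_len(m))]
    if (m > 1) Bcoef[seq_len(m - 1), n] <- sol[bix(seq_len(m - 1))]
  }

  function(points_mm) {
    pts <- points_mm * 1e-3
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
    r <- sqrt(rowSums(pts^2))
    if (any(r > R[1] * (1 + 1e-9)))
      stop("evaluation point outside the outer shell")
    cosa <- pmin(1, pmax(-1, (pts %*% axis) / pmax(r, .Machine$double.xmin)))
    cosa[r == 0] <- 0
    shell <- findInterval(-r, -c(R, 0), rightmost.closed = TRUE)
    shell <- pmin(pmax(shell, 1L), m)
    phi <- numeric(length(r))
    # Legendre recurrences for P_n(cos) and P_n(-cos)
    pm1a <- rep(1, length(r)); pa <- as.numeric(cosa)
    pm1b <- rep(1, length(r)); pb <- -as.numeric(cosa)
    powA <- r * 0; powB <- r * 0
    ratioA <- r / R[shell]                  # (r/R_j)
    ratioB <- ifelse(r > 0, Rin[shell] / r, 0)
    powA <- ratioA; powB <- ratioB^2
    for (n in seq_len(n_terms)) {
      cn <- Acoef[cbind(shell, n)] * powA + Bcoef[cbind(shell, n)] * powB
      phi <- phi + cn * (pa - pb)
      powA <- powA * ratioA; powB <- powB * ratioB
      if (n < n_terms) {                    # advance Legendre recurrence
        pnew_a <- ((2 * n + 1) * as.numeric(cosa) * pa - n * pm1a) / (n + 1)
        pm1a <- pa; pa <- pnew_a
        pnew_b <- ((2 * n + 1) * (-as.numeric(cosa)) * pb - n * pm1b) / (n + 1)
        pm1b <- pb; pb <- pnew_b
      }
    }
    phi
  }
}
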