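# Physical constants, bond-type spring table, and model defaults.

# Unit system: lengths in nm, masses in amu, spring constants in N/m at the
# user surface.  Internally 1 N/m = 602.2140857 amu/ps^2 (1 kg = 6.0221408e26
# amu, 1 s^-2 = 1e-24 ps^-2), so eigenvalues of the mass-weighted Hessian are
# omega^2 in (rad/ps)^2.
AMU_PS2_PER_NM <- 602.2140857

# rad/ps -> cm^-1 (c = 0.0299792458 cm/ps)
CM1_PER_RADPS <- 1 / (2 * pi * 0.0299792458)

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

#' Spring constants per chemical bond type
#'
#' The elastic network assigns one spring constant per bond class, in the
#' ratio 1:10:100 across van der Waals, hydrogen and covalent interactions.
#' Ion and disulfide bonds carry the hydrogen- and covalent-class constants;
#' they are part of the bond-type vocabulary but unused for DNA input.
#'
#' @return Named numeric vector of spring constants in N/m.
#' @export
spring_constants <- function() {
  c(van_der_waals = 7, hydrogen = 70, ion = 70, disulfide = 700, covalent = 700)
}

#' Default model parameters
#'
#' Central registry of the tunable physical parameters: B-form helix
#' geometry, the spring-network cutoff, validation thresholds and solver
#' tolerances.  Values can be overridden per call via the `...` of the
#' builders or by passing a modified copy of this list.
#'
#' @return Named list of defaults:
#' \describe{
#'   \item{rise}{helix rise per base pair, nm (0.34).}
#'   \item{twist}{nominal helix twist per base pair, degrees (34.3, about
#'     10.5 bp/turn).  Arc segments of ring assemblies quantize the twist to
#'     whole turns per tile so the assembly is exactly symmetric.}
#'   \item{cutoff}{van der Waals spring cutoff between beads, nm (0.8).}
#'   \item{clash_dist}{steric clash threshold between non-bonded atoms, nm.}
#'   \item{hbond_band}{acceptable donor-acceptor distance band for
#'     Watson-Crick hydrogen bond sites, nm.}
#'   \item{pair_max_dist}{maximum primary-site distance at which two sticky
#'     overhang bases are considered hybridizable during assembly, nm.}
#'   \item{zero_tol}{relative eigenvalue threshold below which a mode is a
#'     rigid-body (zero) mode.}
#'   \item{mixed_margin}{score margin below which a mode label degrades to
#'     "mixed".}
#' }
#' @export
dnanma_defaults <- function() {
  list(
    rise          = 0.34,
    twist         = 34.3,
    helix_radius  = 0.94,
    cutoff        = 0.8,
    clash_dist    = 0.25,
    hbond_band    = c(0.25, 0.35),
    pair_max_dist = 0.45,
    zero_tol      = 1e-8,
    mixed_margin  = 0.15
  )
}

# Base classification and Watson-Crick complement
PURINES     <- c("A", "G")
PYRIMIDINES <- c("C", "T")
COMPLEMENT  <- c(A = "T", T = "A", G = "C", C = "G")

# Representative atoms per base (plus backbone P, C4', C1'): the glycosidic
# nitrogen and the Watson-Crick edge sites used for hydrogen springs.
BASE_BEADS <- list(
  A = c("N9", "N1", "N6", "C2"),
  G = c("N9", "N1", "O6", "N2"),
  C = c("N1", "N3", "N4"),
  T = c("N1", "N3", "O4")
)

# Watson-Crick hydrogen-bond site pairs (purine atom, pyrimidine atom).
# The third G.C bond (N2-O2) is reported by the validator but carries no
# spring because O2 is not a representative bead.
HBOND_SITES <- list(
  `A.T` = list(c("N1", "N3"), c("N6", "O4")),
  `G.C` = list(c("N1", "N3"), c("O6", "N4"), c("N2", "O2"))
)

# Hydrogen-spring bead pairs (subset of HBOND_SITES restricted to beads)
HSPRING_SITES <- list(
  `A.T` = list(c("N1", "N3"), c("N6", "O4")),
  `G.C` = list(c("N1", "N3"), c("O6", "N4"))
)

# internal: classed error helper
abort_dnanma <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dnanma_error", "error", "condition")))
}
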