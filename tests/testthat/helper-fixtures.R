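# shared fixtures: random MIDs, random derivatized fragments, and the
# exhaustive ISA enumeration oracle

random_mid <- function(n_carbons) {
  f <- stats::rgamma(n_carbons + 1L, shape = 1)
  mid(f / sum(f), n_carbons = n_carbons, corrected = TRUE)
}

random_fragment <- function(max_backbone = 6L) {
  n <- sample(2:max_backbone, 1L)
  fragment_formula(
    c(C = n + sample(0:10, 1L), H = sample(0:30, 1L),
      N = sample(0:2, 1L), O = sample(0:5, 1L),
      Si = sample(0:3, 1L), S = sample(0:1, 1L)),
    n_backbone_carbons = n
  )
}

# exhaustive enumeration over all 3^n_units acetyl-unit assignments:
# the independent oracle for the ISA forward model
isa_states_8 <- as.matrix(expand.grid(rep(list(0:2), 8)))

brute_force_fatty_acid <- function(X, Nnat, g, n_units = 8L) {
  stopifnot(n_units == 8L)
  enumerate <- function(acetyl) {
    p <- apply(isa_states_8, 1L, function(s) prod(acetyl[s + 1L]))
    mass <- rowSums(isa_states_8)
    out <- numeric(2L * 8L + 1L)
    for (m in unique(mass)) out[m + 1L] <- sum(p[mass == m])
    out
  }
  g * enumerate(X) + (1 - g) * enumerate(Nnat)
}
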