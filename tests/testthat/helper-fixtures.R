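# shared fixtures: example specs and constraint-respecting random draws

mudl_example <- function()
  model_spec("modified_udl", c(amu = 0.6, bmu = 0.2, cmu = 0.9, dmu = 1))

udl_example <- function()
  model_spec("udl", c(au = 0.5, bu = 0.2, du = 1))

protocol_schedule <- function(proto = protocol()) build_protocol(proto)

# one random spec satisfying the family's validity constraints;
# caller is responsible for seeding the RNG
random_valid_spec <- function(family) {
  switch(family,
    single_state = model_spec("single_state", c(
      a_prime = runif(1, -0.99, 0.99), b_prime = runif(1, -1, 1),
      c = runif(1, -2, 2), d = runif(1, -2, 2))),
    udl = {
      repeat {
        au <- runif(1, 0, 1); bu <- runif(1, -1, 1)
        if (abs(au + bu) < 0.999) break
      }
      model_spec("udl", c(au = au, bu = bu, du = runif(1, -2, 2)))
    },
    fast_slow = {
      af <- runif(1, 0.01, 0.9)
      as_ <- runif(1, af + 0.01, 1)
      bf <- runif(1, -0.9, 1)
      bs <- runif(1, -1, bf - 0.01)
      model_spec("fast_slow", c(af = af, bf = bf, as = as_, bs = bs,
                                d = runif(1, -2, 2)))
    },
    modified_udl = {
      repeat {
        amu <- runif(1, 0, 1); bmu <- runif(1, -1, 1); cmu <- runif(1, 0, 1)
        if (abs(amu + bmu + cmu - 1) < 0.999) break
      }
      model_spec("modified_udl", c(amu = amu, bmu = bmu, cmu = cmu,
                                   dmu = runif(1, -2, 2)))
    },
    two_state = {
      A <- matrix(runif(4, -1, 1), 2, 2)
      rho <- max(Mod(eigen(A, only.values = TRUE)$values))
      if (rho > 0.98) A <- A * 0.98 / rho
      model_spec("two_state", c(a11 = A[1, 1], a12 = A[1, 2], a21 = A[2, 1],
                                a22 = A[2, 2], b1 = runif(1, -1, 1),
                                b2 = runif(1, -1, 1), c1 = runif(1, -1, 1),
                                c2 = runif(1, -1, 1), d = runif(1, -2, 2)))
    })
}
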