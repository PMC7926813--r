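# Shared oracles and fixture builders for the suite.

EPS0_T <- 8.8541878128e-12

sigma_at <- function(eps, f) 2 * pi * f * EPS0_T * -Im(eps)

# central finite differences of the mixture permittivity w.r.t. v2 and nacl
fd_mixture_derivs <- function(frequencies, v2, nacl, law,
                              h_v2 = 1e-6, h_rel_s = 1e-4) {
  hs <- max(nacl, 1) * h_rel_s
  list(
    d_v2 = (mixture_permittivity(frequencies, v2 + h_v2, nacl, law = law) -
              mixture_permittivity(frequencies, v2 - h_v2, nacl, law = law)) /
      (2 * h_v2),
    d_nacl = (mixture_permittivity(frequencies, v2, nacl + hs, law = law) -
                mixture_permittivity(frequencies, v2, nacl - hs, law = law)) /
      (2 * hs)
  )
}

# random passive permittivities (right half-plane, eps'' >= 0)
random_passive_eps <- function(n) {
  complex(real = runif(n, 1.5, 80), imaginary = -runif(n, 0, 40))
}

# regular tetrahedron as an n x 3 x 3 triangle array (watertight mesh)
tetra_triangles <- function(scale = 10) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * scale
  faces <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  tri <- array(NA_real_, c(4, 3, 3))
  for (i in 1:4) tri[i, , ] <- v[faces[i, ], ]
  tri
}

write_ascii_stl_fixture <- function(path, tri = tetra_triangles()) {
  write_stl(tri, path, format = "ascii")
  path
}
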