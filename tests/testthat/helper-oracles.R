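# Independent pure-R oracles and small fixture builders.  These deliberately
# avoid the package's computational kernels so that tests compare two
# independent routes.

# all-pairs contact count, plain R, strict '<'
r_count_contacts <- function(xa, xb, cutoff, box = NULL) {
  n <- 0L
  for (i in seq_len(nrow(xa))) {
    d <- sweep(xb, 2L, xa[i, ])
    if (!is.null(box)) for (k in 1:3) d[, k] <- d[, k] -
        box[k] * round(d[, k] / box[k])
    n <- n + sum(sqrt(rowSums(d^2)) < cutoff)
  }
  n
}

# direct pair-sum nonbonded energy, plain R
r_pair_energy <- function(coords, ia, ib, q, sig, eps, cutoff,
                          k_e = 1389.35458) {
  ec <- 0; el <- 0
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d >= cutoff) next
    ec <- ec + k_e * q[i] * q[j] / d
    sij <- (sig[i] + sig[j]) / 2
    eij <- sqrt(eps[i] * eps[j])
    el <- el + 4 * eij * ((sij / d)^12 - (sij / d)^6)
  }
  c(ec, el)
}

# random point cloud in a box of side L
random_cloud <- function(n, L = 20) {
  matrix(runif(n * 3, 0, L), ncol = 3)
}

# minimal all-carbon topology for n coordinates
carbon_topology <- function(n, resname = "ALA", segment = "protein") {
  topology(name = rep("CA", n), resname = resname, resid = seq_len(n),
           chain = "A", element = "C", segment = segment)
}

# tiny mixed protein + lipid fixture with known composition
tiny_system <- function() {
  name <- c("N", "CA", "C", "O", "CB", "CG",      # PHE 2093
            "N", "CA", "C", "O", "NH1",           # ARG 2163
            "N", "C11", "C12", "C13", "C14", "C15", "P",
            "O11", "O12", "O13", "O14",
            "O21", "O22", "O31", "O32", "C1", "C2", "C3", "C22", "C23",
            "C32",                                # DOPC 1
            "N", "C11", "C12", "C13", "O13A", "O13B", "P",
            "O11", "O12", "O13", "O14",
            "O21", "O22", "O31", "O32", "C1", "C2", "C3", "C22", "C32")
  resname <- c(rep("PHE", 6), rep("ARG", 5), rep("DOPC", 21),
               rep("DOPS", 20))
  resid <- c(rep(2093L, 6), rep(2163L, 5), rep(1L, 21), rep(2L, 20))
  chain <- c(rep("A", 11), rep("L", 41))
  top <- topology(name = name, resname = resname, resid = resid,
                  chain = chain)
  coords <- matrix(rnorm(length(name) * 3, sd = 5), ncol = 3)
  list(topology = top, frame = frame(coords))
}

# small shared synthetic trajectory for cross-module tests (memoised)
.shared_gen <- local({
  cache <- NULL
  function(n_frames = 300, seed = 11) {
    if (is.null(cache)) {
      nano <- build_nanodisc(seed = 1)
      probe <- build_probe_protein(1)
      cache <<- generate_binding_trajectory(nano, probe,
                                            n_frames = n_frames,
                                            seed = seed)
    }
    cache
  }
})
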