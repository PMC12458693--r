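# Shared fixtures and an independent (pure-R) reference energy used as the
# brute-force oracle for the compiled engine.

P298 <- energy_params()

# pure-R reimplementation of the full potential: naive double loops, no code
# shared with the compiled path beyond the water-model constants
ref_water_sites <- function(oxygen, quat, model) {
  R <- quat_to_matrix(quat)
  sweep(model$site_offsets %*% t(R), 2, oxygen, "+")
}

ref_switch <- function(r, params) {
  rc <- params$cutoff; ron <- rc - params$switch_width
  if (r <= ron) return(1)
  if (r >= rc) return(0)
  (rc^2 - r^2)^2 * (rc^2 + 2 * r^2 - 3 * ron^2) / (rc^2 - ron^2)^3
}

ref_lj <- function(r, sig, eps) {
  if (sig <= 0 || eps <= 0) return(0)
  4 * eps * ((sig / r)^12 - (sig / r)^6)
}

ref_total_energy <- function(host, waters, model, params, region) {
  n <- nrow(waters)
  sites <- lapply(seq_len(n), function(i)
    ref_water_sites(waters[i, 1:3], waters[i, 4:7], model))
  hm <- host$sites
  e <- 0
  for (i in seq_len(n)) {
    o <- waters[i, 1:3]
    # host-water, molecule switching on the oxygen-site distance
    for (j in seq_len(nrow(hm))) {
      hx <- c(hm$x[j], hm$y[j], hm$z[j])
      ro <- sqrt(sum((o - hx)^2))
      if (ro >= params$cutoff) next
      ej <- ref_lj(ro, (hm$sigma[j] + model$oxygen_lj_sigma) / 2,
                   sqrt(hm$epsilon[j] * model$oxygen_lj_epsilon))
      if (hm$charge[j] != 0) {
        for (s in seq_len(nrow(sites[[i]]))) {
          if (model$site_charges[s] == 0) next
          rs <- sqrt(sum((sites[[i]][s, ] - hx)^2))
          ej <- ej + params$coulomb_constant * hm$charge[j] *
            model$site_charges[s] / rs
        }
      }
      e <- e + ej * ref_switch(ro, params)
    }
    # restraint
    d <- sqrt(sum((o - region$droplet_center)^2))
    if (d > region$droplet_radius)
      e <- e + 0.5 * region$restraint_k * (d - region$droplet_radius)^2
    # water-water
    for (k in seq_len(n)) {
      if (k <= i) next
      roo <- sqrt(sum((o - waters[k, 1:3])^2))
      if (roo >= params$cutoff) next
      ew <- ref_lj(roo, model$oxygen_lj_sigma, model$oxygen_lj_epsilon)
      for (s in seq_len(nrow(sites[[i]]))) {
        if (model$site_charges[s] == 0) next
        for (t in seq_len(nrow(sites[[k]]))) {
          if (model$site_charges[t] == 0) next
          rst <- sqrt(sum((sites[[i]][s, ] - sites[[k]][t, ])^2))
          ew <- ew + params$coulomb_constant * model$site_charges[s] *
            model$site_charges[t] / rst
        }
      }
      e <- e + ew * ref_switch(roo, params)
    }
  }
  e
}

# a random-but-reproducible water configuration inside a box
rand_waters <- function(n, box, seed) {
  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }
  with_seed(seed, {
    ox <- cbind(runif(n, box$min[1], box$max[1]),
                runif(n, box$min[2], box$max[2]),
                runif(n, box$min[3], box$max[3]))
    water_matrix(ox, random_rotations(n))
  })
}

# tiny far-away host so host terms are ~0 where a pure water box is wanted
null_host <- function() {
  host_structure(particle_sites(matrix(c(500, 500, 500), 1)))
}
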