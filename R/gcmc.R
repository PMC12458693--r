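#' Move schedule for a GCMC run
#'
#' Move-type probabilities, step sizes, and run lengths.  Insertion and
#' deletion act inside the GCMC box; displacement moves act on box waters or
#' bulk (outside-box) waters and reject any move that carries an oxygen
#' across the box boundary, so insertion/deletion are the only moves that
#' change the region count.
#'
#' @param n_production production moves
#' @param sample_interval moves between samples; must divide
#'   \code{n_production}
#' @param n_equil_region first-phase equilibration moves (region-only
#'   sampling: insertion, deletion, region displacement)
#' @param n_equil_all second-phase equilibration moves (all move types)
#' @param p_insert,p_delete,p_displace_region,p_displace_bulk move-type
#'   probabilities; must be >= 0 and sum to 1
#' @param max_translate maximum displacement step per axis in Angstrom
#' @param max_rotate maximum rotation step in radians
#' @param swap_interval moves between replica-exchange attempts in ladder
#'   runs
#' @return an object of class \code{move_schedule}
#' @export
move_schedule <- function(n_production = 50000, sample_interval = 50,
                          n_equil_region = 10000, n_equil_all = 5000,
                          p_insert = 0.35, p_delete = 0.35,
                          p_displace_region = 0.2, p_displace_bulk = 0.1,
                          max_translate = 0.25, max_rotate = pi / 4,
                          swap_interval = 5000) {
  p <- c(p_insert, p_delete, p_displace_region, p_displace_bulk)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("move probabilities must be >= 0 and sum to 1")
  if (n_production > 0 && n_production %% sample_interval != 0)
    stop("sample_interval must divide n_production")
  structure(list(n_production = n_production, sample_interval = sample_interval,
                 n_equil_region = n_equil_region, n_equil_all = n_equil_all,
                 probs = p, max_translate = max_translate,
                 max_rotate = max_rotate, swap_interval = swap_interval),
            class = "move_schedule")
}

#' Desk-scale and full-scale schedule presets
#'
#' \code{desk_schedule()} is sized for laptop-scale synthetic systems;
#' \code{paper_schedule()} carries the full-scale settings (5M + 5M
#' equilibration, 40M production, sampling and replica exchange every 100k
#' moves) appropriate for cluster runs on real complexes.
#'
#' @param ... overrides passed to [move_schedule()]
#' @return a \code{move_schedule}
#' @export
desk_schedule <- function(...) {
  modify_schedule(move_schedule(), list(...))
}

#' @rdname desk_schedule
#' @export
paper_schedule <- function(...) {
  modify_schedule(move_schedule(n_production = 4e7, sample_interval = 1e5,
                                n_equil_region = 5e6, n_equil_all = 5e6,
                                swap_interval = 1e5), list(...))
}

modify_schedule <- function(sched, overrides) {
  if (length(overrides) == 0) return(sched)
  args <- utils::modifyList(
    list(n_production = sched$n_production, sample_interval = sched$sample_interval,
         n_equil_region = sched$n_equil_region, n_equil_all = sched$n_equil_all,
         p_insert = sched$probs[1], p_delete = sched$probs[2],
         p_displace_region = sched$probs[3], p_displace_bulk = sched$probs[4],
         max_translate = sched$max_translate, max_rotate = sched$max_rotate,
         swap_interval = sched$swap_interval),
    overrides)
  do.call(move_schedule, args)
}

#' Adams B-value ladder
#'
#' Default: 24 values from -19.0 to -7.5 in steps of 0.5.
#'
#' @param from,to,by ladder limits and spacing
#' @return numeric vector of B values (ascending)
#' @export
b_ladder <- function(from = -19, to = -7.5, by = 0.5) {
  seq(from, to, by = by)
}

#' GCMC state at one B value
#'
#' The unit the engine evolves: a rigid host plus a variable-size set of
#' rigid waters, the Adams B value, energy parameters, region, an
#' independent RNG stream derived from \code{(seed, stream)}, and move
#' counters.
#'
#' @param host a \code{host_structure}
#' @param model a \code{water_model}
#' @param region a \code{simulation_region}
#' @param params an \code{energy_params}
#' @param B Adams chemical-potential parameter (dimensionless)
#' @param seed master seed
#' @param stream stream index (use distinct streams for replicas/repeats)
#' @param waters optional starting configuration ([water_matrix()])
#' @return an object of class \code{gcmc_state}
#' @export
gcmc_state <- function(host, model, region, params, B, seed = 1, stream = 0,
                       waters = NULL) {
  waters <- waters %||% water_matrix(NULL)
  structure(list(host = host, model = model, region = region, params = params,
                 B = B, waters = waters,
                 rng_state = cpp_rng_create(seed, stream),
                 seed = seed, stream = stream,
                 u_total = NA_real_,
                 n_region = sum(in_gcmc_box(waters[, 1:3, drop = FALSE], region)),
                 attempted = numeric(4), accepted = numeric(4)),
            class = "gcmc_state")
}

# advance a state by n_moves; updates configuration, energy, rng, counters
gcmc_chunk <- function(state, n_moves, probs, sample_interval = 0,
                       record_frames = FALSE, check_energy = FALSE,
                       max_translate, max_rotate) {
  if (n_moves <= 0) {
    return(list(state = state,
                sample_N = integer(0), sample_U = numeric(0),
                frames = matrix(numeric(0), ncol = 4,
                                dimnames = list(NULL, c("frame", "x", "y", "z"))),
                max_drift = 0))
  }
  res <- cpp_gcmc_chunk(site_matrix(state$host$sites), unclass(state$model),
                        params_vector(state$params), region_vector(state$region),
                        state$waters, state$B, probs, max_translate, max_rotate,
                        as.integer(n_moves), as.integer(sample_interval),
                        record_frames, state$rng_state, state$u_total,
                        check_energy)
  state$waters <- res$waters
  state$rng_state <- res$rng_state
  state$u_total <- res$u_total
  state$n_region <- res$n_region
  state$attempted <- state$attempted + res$attempted
  state$accepted <- state$accepted + res$accepted
  list(state = state, sample_N = res$sample_N, sample_U = res$sample_U,
       frames = res$frames, max_drift = res$max_drift)
}

region_only_probs <- function(probs) {
  p <- c(probs[1:3], 0)
  p / sum(p)
}

#' Run a single-B GCMC simulation
#'
#' Two-phase equilibration (region-only sampling, then all waters) followed
#' by production with samples recorded every \code{sample_interval} moves.
#' Fully reproducible from \code{(seed, stream)}.
#'
#' @param state a [gcmc_state()]
#' @param schedule a [move_schedule()]
#' @param record_frames keep region-water oxygen coordinates per sample
#' @param check_energy recompute the total energy at every sample and track
#'   the maximum deviation from the running incremental energy
#' @return an object of class \code{gcmc_trajectory} with per-sample region
#'   counts \code{N}, total energies \code{U}, frame coordinates, move
#'   counters and the final state
#' @export
run_gcmc <- function(state, schedule, record_frames = TRUE,
                     check_energy = FALSE) {
  stopifnot(inherits(state, "gcmc_state"), inherits(schedule, "move_schedule"))
  c1 <- gcmc_chunk(state, schedule$n_equil_region, region_only_probs(schedule$probs),
                   max_translate = schedule$max_translate,
                   max_rotate = schedule$max_rotate)
  c2 <- gcmc_chunk(c1$state, schedule$n_equil_all, schedule$probs,
                   max_translate = schedule$max_translate,
                   max_rotate = schedule$max_rotate)
  c3 <- gcmc_chunk(c2$state, schedule$n_production, schedule$probs,
                   sample_interval = schedule$sample_interval,
                   record_frames = record_frames, check_energy = check_energy,
                   max_translate = schedule$max_translate,
                   max_rotate = schedule$max_rotate)
  new_gcmc_trajectory(c3, state$B, state$seed, state$stream, schedule)
}

new_gcmc_trajectory <- function(chunk, B, seed, stream, schedule,
                                repeat_id = 1L) {
  structure(list(N = chunk$sample_N, U = chunk$sample_U, frames = chunk$frames,
                 n_frames = length(chunk$sample_N), B = B, seed = seed,
                 stream = stream, repeat_id = repeat_id, schedule = schedule,
                 attempted = chunk$state$attempted,
                 accepted = chunk$state$accepted,
                 max_drift = chunk$max_drift,
                 final_state = chunk$state),
            class = "gcmc_trajectory")
}

#' @export
print.gcmc_trajectory <- function(x, ...) {
  cat("<gcmc_trajectory> B =", x$B, ":", x$n_frames, "samples, <N> =",
      if (x$n_frames) round(mean(x$N), 3) else NA, "\n")
  invisible(x)
}

#' One replica-exchange sweep across a B ladder
#'
#' Attempts configuration swaps between adjacent pairs \code{(m, n)} with
#' probability \eqn{\min(1, \exp[(B_m - B_n)(N_n - N_m)])}; pairing
#' alternates between even and odd adjacent pairs across sweeps.  Uses R's
#' RNG for the acceptance draws (seed it for reproducibility).
#'
#' @param states list of \code{gcmc_state}s at strictly increasing B
#' @param parity 0 starts pairing at the first state, 1 at the second
#' @return list with updated \code{states}, and \code{attempted} /
#'   \code{accepted} swap counts per adjacent pair
#' @export
replica_exchange_sweep <- function(states, parity = 0) {
  n <- length(states)
  attempted <- accepted <- numeric(max(n - 1, 0))
  if (n >= 2) {
    Bs <- vapply(states, function(s) s$B, numeric(1))
    if (any(diff(Bs) <= 0)) stop("replica B values must be strictly increasing")
    first <- 1 + (parity %% 2)
    for (m in seq(first, n - 1, by = 2)) {
      k <- m + 1
      attempted[m] <- attempted[m] + 1
      logp <- (states[[m]]$B - states[[k]]$B) *
        (states[[k]]$n_region - states[[m]]$n_region)
      if (log(runif(1)) < logp) {
        accepted[m] <- accepted[m] + 1
        swap <- c("waters", "u_total", "n_region")
        tmp <- states[[m]][swap]
        states[[m]][swap] <- states[[k]][swap]
        states[[k]][swap] <- tmp
      }
    }
  }
  list(states = states, attempted = attempted, accepted = accepted)
}

#' Run a replica-exchange GCMC ladder with repeats
#'
#' One replica per B value; production proceeds in chunks of
#' \code{schedule$swap_interval} moves with replica-exchange sweeps between
#' chunks (alternating pair parity).  Repeats use independent RNG streams
#' derived from the master seed.
#'
#' @inheritParams gcmc_state
#' @param B_values ascending B ladder, e.g. [b_ladder()]
#' @param schedule a [move_schedule()]
#' @param n_repeats independent repeats (default 3)
#' @param replica_exchange attempt swaps between adjacent B values
#' @param record_frames keep frame coordinates (needed for clustering)
#' @return an object of class \code{gcmc_ladder}: list of
#'   \code{gcmc_trajectory} (one per B per repeat), the ladder, and swap
#'   acceptance statistics
#' @export
run_gcmc_ladder <- function(host, model, region, params, B_values,
                            schedule = desk_schedule(), seed = 1,
                            n_repeats = 3, replica_exchange = TRUE,
                            record_frames = FALSE) {
  stopifnot(length(B_values) >= 1, !is.unsorted(B_values, strictly = TRUE))
  nB <- length(B_values)
  trajectories <- vector("list", nB * n_repeats)
  swap_att <- swap_acc <- numeric(max(nB - 1, 0))

  for (r in seq_len(n_repeats)) {
    states <- lapply(seq_len(nB), function(i) {
      gcmc_state(host, model, region, params, B_values[i], seed = seed,
                 stream = (r - 1) * 1000 + i)
    })
    # two-phase equilibration per replica
    states <- lapply(states, function(s) {
      s <- gcmc_chunk(s, schedule$n_equil_region, region_only_probs(schedule$probs),
                      max_translate = schedule$max_translate,
                      max_rotate = schedule$max_rotate)$state
      gcmc_chunk(s, schedule$n_equil_all, schedule$probs,
                 max_translate = schedule$max_translate,
                 max_rotate = schedule$max_rotate)$state
    })
    # production in swap-interval chunks
    n_chunks <- if (replica_exchange && nB > 1) {
      max(1, ceiling(schedule$n_production / schedule$swap_interval))
    } else 1
    base <- floor(schedule$n_production / n_chunks / schedule$sample_interval) *
      schedule$sample_interval
    chunk_moves <- rep(base, n_chunks)
    rem <- schedule$n_production - sum(chunk_moves)
    if (rem > 0) chunk_moves[n_chunks] <- chunk_moves[n_chunks] + rem

    acc <- lapply(seq_len(nB), function(i)
      list(N = integer(0), U = numeric(0), frames = NULL, drift = 0))
    with_seed(derive_seed(seed, 777 + r), {
      for (ch in seq_len(n_chunks)) {
        for (i in seq_len(nB)) {
          res <- gcmc_chunk(states[[i]], chunk_moves[ch], schedule$probs,
                            sample_interval = schedule$sample_interval,
                            record_frames = record_frames,
                            max_translate = schedule$max_translate,
                            max_rotate = schedule$max_rotate)
          states[[i]] <- res$state
          off <- length(acc[[i]]$N)
          acc[[i]]$N <- c(acc[[i]]$N, res$sample_N)
          acc[[i]]$U <- c(acc[[i]]$U, res$sample_U)
          if (record_frames && nrow(res$frames) > 0) {
            fr <- res$frames
            fr[, 1] <- fr[, 1] + off
            acc[[i]]$frames <- rbind(acc[[i]]$frames, fr)
          }
        }
        if (replica_exchange && nB > 1 && ch < n_chunks) {
          sw <- replica_exchange_sweep(states, parity = ch %% 2)
          states <- sw$states
          swap_att <- swap_att + sw$attempted
          swap_acc <- swap_acc + sw$accepted
        }
      }
    })
    for (i in seq_len(nB)) {
      fr <- acc[[i]]$frames %||%
        matrix(numeric(0), ncol = 4,
               dimnames = list(NULL, c("frame", "x", "y", "z")))
      trajectories[[(r - 1) * nB + i]] <- structure(
        list(N = acc[[i]]$N, U = acc[[i]]$U, frames = fr,
             n_frames = length(acc[[i]]$N), B = B_values[i], seed = seed,
             stream = states[[i]]$stream, repeat_id = r, schedule = schedule,
             attempted = states[[i]]$attempted, accepted = states[[i]]$accepted,
             max_drift = 0, final_state = states[[i]]),
        class = "gcmc_trajectory")
    }
  }

  structure(list(trajectories = trajectories, B = B_values,
                 n_repeats = n_repeats,
                 swap_attempted = swap_att, swap_accepted = swap_acc,
                 seed = seed),
            class = "gcmc_ladder")
}

#' @export
print.gcmc_ladder <- function(x, ...) {
  cat("<gcmc_ladder>", length(x$B), "B values x", x$n_repeats, "repeats\n")
  if (length(x$swap_attempted) && sum(x$swap_attempted) > 0)
    cat("  mean swap acceptance:",
        round(sum(x$swap_accepted) / sum(x$swap_attempted), 3), "\n")
  invisible(x)
}
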