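WATER_RESIDUES <- c("HOH", "WAT")
WATER_OXYGEN_NAMES <- c("O", "OW")

#' Read a host structure from PDB plus a parameter sidecar
#'
#' PDB carries no force-field data, so LJ/charge parameters come from a
#' columnar sidecar file with one row per non-water atom (in file order):
#' \code{index sigma epsilon charge}.  Water residues (HOH/WAT, oxygen
#' atom names O/OW) are collected as crystallographic water oxygens and
#' excluded from the interaction sites.
#'
#' @param path PDB file
#' @param parameter_sidecar sidecar text file; NULL gives all-zero
#'   parameters (geometry-only host)
#' @return a \code{host_structure}
#' @export
read_host_pdb <- function(path, parameter_sidecar = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  is_water <- at$resid %in% WATER_RESIDUES
  crystal <- at[is_water & at$elety %in% WATER_OXYGEN_NAMES,
                c("x", "y", "z"), drop = FALSE]
  solute <- at[!is_water, , drop = FALSE]
  if (nrow(solute) == 0) stop("PDB contains no non-water atoms")
  n <- nrow(solute)
  if (!is.null(parameter_sidecar)) {
    par <- read.table(parameter_sidecar, header = TRUE)
    need <- c("index", "sigma", "epsilon", "charge")
    if (!all(need %in% names(par)))
      stop("parameter sidecar must have columns: ", paste(need, collapse = ", "))
    if (nrow(par) != n) {
      miss <- if (nrow(par) < n) solute[nrow(par) + 1, ] else NULL
      stop("parameter sidecar has ", nrow(par), " rows for ", n,
           " non-water atoms",
           if (!is.null(miss)) paste0("; first unparametrised atom: ",
                                      miss$elety, " ", miss$resid, " ",
                                      miss$resno) else "")
    }
    par <- par[order(par$index), ]
    sites <- particle_sites(as.matrix(solute[, c("x", "y", "z")]),
                            lj_sigma = par$sigma, lj_epsilon = par$epsilon,
                            charge = par$charge, label = solute$elety)
  } else {
    sites <- particle_sites(as.matrix(solute[, c("x", "y", "z")]),
                            label = solute$elety)
  }
  host_structure(sites, crystal_water_oxygens = as.matrix(crystal))
}

#' Write a host structure as PDB plus a parameter sidecar
#'
#' @param host a \code{host_structure}
#' @param path output PDB path
#' @param sidecar_path output sidecar path (optional)
#' @return \code{path}, invisibly
#' @export
write_host_pdb <- function(host, path, sidecar_path = NULL) {
  s <- host$sites
  n <- nrow(s)
  cw <- host$crystal_water_oxygens
  lines <- character(0)
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, substr(paste0("S", i), 1, 4), "CGE", i, s$x[i], s$y[i], s$z[i], 1, 0))
  }
  for (j in seq_len(nrow(cw))) {
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      n + j, "O", "HOH", n + j, cw[j, 1], cw[j, 2], cw[j, 3], 1, 0))
  }
  writeLines(c(lines, "END"), path)
  if (!is.null(sidecar_path)) {
    write.table(data.frame(index = seq_len(n), sigma = s$sigma,
                           epsilon = s$epsilon, charge = s$charge),
                sidecar_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write region-water frames as a multi-model PDB
#'
#' Water oxygens only, one MODEL per stored frame; occupancy column 1.00.
#' Readable back with [read_trajectory_pdb()].
#'
#' @param traj a \code{gcmc_trajectory} (or frames matrix)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_trajectory_pdb <- function(traj, path) {
  frames <- if (inherits(traj, "gcmc_trajectory")) traj$frames else traj
  n_frames <- if (inherits(traj, "gcmc_trajectory")) traj$n_frames else max(frames[, 1], 0)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    rows <- which(frames[, 1] == f)
    for (k in seq_along(rows)) {
      r <- frames[rows[k], ]
      writeLines(sprintf(
        "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
        k, k, r[2], r[3], r[4], 1, 0), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model water PDB back into a frames matrix
#' @param path PDB written by [write_trajectory_pdb()]
#' @return frames matrix (columns \code{frame, x, y, z}) with attribute
#'   \code{n_frames}
#' @export
read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  frame <- 0
  rows <- list()
  n_frames <- 0
  for (ln in lines) {
    if (startsWith(ln, "MODEL")) {
      frame <- as.integer(substr(ln, 6, 14))
      n_frames <- max(n_frames, frame)
    } else if (startsWith(ln, "HETATM") || startsWith(ln, "ATOM")) {
      rows[[length(rows) + 1]] <- c(frame,
                                    as.numeric(substr(ln, 31, 38)),
                                    as.numeric(substr(ln, 39, 46)),
                                    as.numeric(substr(ln, 47, 54)))
    }
  }
  out <- do.call(rbind, rows) %||% matrix(numeric(0), ncol = 4)
  colnames(out) <- c("frame", "x", "y", "z")
  attr(out, "n_frames") <- n_frames
  out
}

#' Write clustered hydration sites as a PDB of pseudo-atoms
#'
#' Occupancy goes in the B-factor column (as a percentage), the
#' field-standard way to carry per-site occupancies in PDB viewers.
#'
#' @param clusters a \code{water_sites} table
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_sites_pdb <- function(clusters, path) {
  lines <- vapply(seq_len(nrow(clusters)), function(i) {
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
            i, i, clusters$x[i], clusters$y[i], clusters$z[i], 1,
            100 * clusters$occupancy[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write per-sample GCMC records as columnar text
#'
#' Columns: sample index, B, N, total energy.
#'
#' @param traj a \code{gcmc_trajectory}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_samples <- function(traj, path) {
  df <- data.frame(sample = seq_along(traj$N), B = traj$B, N = traj$N,
                   energy = traj$U)
  write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
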