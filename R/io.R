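# Formats and configuration: PDB reference import (coarse-graining to the
# two-site bead model), extended-XYZ trajectory round-trip with a JSON
# metadata sidecar, PDB snapshot export, and the declarative run
# configuration with hashing for reproducible manifests.

#' Coarse-grain a PDB structure into a fibril reference
#'
#' Reads a PDB file (first chain by default), maps CA atoms to backbone beads
#' and side-chain heavy-atom centroids to side-chain beads (glycine or
#' side-chain-less residues get the SC bead at CA plus a small offset, with a
#' warning), and builds the backbone pair list over the resolved residues
#' only.  Bead indices in the pair list follow the interleaved convention
#' (residue `r` -> BB bead `2r - 1`) using the PDB residue numbers, so the
#' reference plugs into full-length simulated chains directly.
#'
#' @param path PDB file path.
#' @param chain chain identifier (default: first chain present).
#' @param d overlap tolerance, Angstrom.
#' @param label reference label (default: file name).
#' @param min_sep minimum residue separation for the pair list.
#' @return a [reference_structure()]; attribute `"resno"` lists the resolved
#'   residue numbers.
#' @export
read_reference_pdb <- function(path, chain = NULL, d = 2, label = NULL,
                               min_sep = 3L) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("PDB parse error in '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain & !is.na(at$resno), ]
  ca <- at[at$elety == "CA", ]
  if (nrow(ca) == 0L) stop("no CA records in '", path, "' chain ", chain)
  ca <- ca[!duplicated(ca$resno), ]
  resno <- ca$resno
  bb <- as.matrix(ca[, c("x", "y", "z")])
  sc <- matrix(NA_real_, length(resno), 3)
  nosc <- 0L
  for (k in seq_along(resno)) {
    side <- at[at$resno == resno[k] &
                 !at$elety %in% c("N", "CA", "C", "O", "OXT") &
                 at$elesy != "H", ]
    if (nrow(side) == 0L) {
      sc[k, ] <- bb[k, ] + c(0, 0, 1)
      nosc <- nosc + 1L
    } else {
      sc[k, ] <- colMeans(as.matrix(side[, c("x", "y", "z")]))
    }
  }
  if (nosc > 0L)
    warning(nosc, " residue(s) without side-chain atoms; SC bead placed at ",
            "CA + 1 Angstrom offset")
  # interleaved bead coordinates indexed by residue number
  nmax <- max(resno)
  coords <- matrix(NA_real_, 2L * nmax, 3L)
  coords[2L * resno - 1L, ] <- bb
  coords[2L * resno, ] <- sc
  pr <- which(outer(resno, resno, function(a, b) b - a) >= min_sep,
              arr.ind = TRUE)
  i <- 2L * resno[pr[, 1]] - 1L
  j <- 2L * resno[pr[, 2]] - 1L
  r0 <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  ref <- reference_structure(coords = coords,
                             pair_list = data.frame(i = i, j = j, r0 = r0),
                             d = d,
                             label = if (is.null(label))
                               sub("\\.pdb$", "", basename(path)) else label)
  attr(ref, "resno") <- resno
  ref
}

#' Export/import a reference pair list as TSV
#' @param ref a [reference_structure()] (for export).
#' @param path TSV path.
#' @return [write_pair_list()]: the path, invisibly; [read_pair_list()]: a
#'   `reference_structure` built from the table.
#' @export
write_pair_list <- function(ref, path) {
  utils::write.table(cbind(ref$pair_list, d = ref$d, label = ref$label),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pair_list
#' @export
read_pair_list <- function(path) {
  tb <- utils::read.delim(path)
  reference_structure(pair_list = tb[, c("i", "j", "r0")], d = tb$d[1],
                      label = as.character(tb$label[1]))
}

#' Write a trajectory as extended XYZ with a JSON sidecar
#'
#' Coordinates go to `path` in extended-XYZ (species column `BB`/`SC` when a
#' topology is given, else `X`); frame metadata (frame spacing, duration,
#' seed, config hash, units) goes to `paste0(path, ".json")`.  Reading
#' requires the sidecar.
#'
#' @param traj an `sop_trajectory`.
#' @param path output file.
#' @param topo optional topology for species labels.
#' @return invisibly, the two file paths.
#' @export
write_trajectory_xyz <- function(traj, path, topo = NULL) {
  fr <- trajectory_frames(traj)
  nf <- dim(fr)[1]; nb <- dim(fr)[2]
  species <- if (is.null(topo)) rep("X", nb) else topo$beads$site
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(nf)) {
    writeLines(as.character(nb), con)
    writeLines(sprintf('Lattice="" Properties=species:S:1:pos:R:3 time=%.6f',
                       (t - 1) * traj$dt_save_ps), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", species, fr[t, , 1], fr[t, , 2],
                       fr[t, , 3]), con)
  }
  meta <- list(format = "extended-xyz", n_frames = nf, n_beads = nb,
               dt_save_ps = traj$dt_save_ps, duration_ps = traj$duration_ps,
               seed = traj$cfg$seed, config_hash = config_hash(traj$cfg),
               units = list(length = "Angstrom", time = "ps",
                            energy = "kcal/mol"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, paste0(path, ".json")))
}

#' Read an extended-XYZ trajectory written by [write_trajectory_xyz()]
#'
#' @param path XYZ file; the `.json` sidecar must sit beside it.
#' @return object of class `sop_trajectory` (frames + metadata; `cfg` holds
#'   the stored seed and hash only).
#' @export
read_trajectory_xyz <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar metadata file: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  lines <- readLines(path)
  nb <- as.integer(lines[1])
  per <- nb + 2L
  nf <- length(lines) %/% per
  if (nf != meta$n_frames || nb != meta$n_beads)
    stop("trajectory/sidecar mismatch: file has ", nf, " frames x ", nb,
         " beads, sidecar says ", meta$n_frames, " x ", meta$n_beads)
  frames <- array(NA_real_, c(nf, nb, 3))
  for (t in seq_len(nf)) {
    block <- lines[((t - 1) * per + 3):((t - 1) * per + 2 + nb)]
    m <- do.call(rbind, strsplit(block, " ", fixed = TRUE))
    frames[t, , ] <- matrix(as.numeric(m[, 2:4]), nb, 3)
  }
  structure(list(frames = frames, dt_save_ps = meta$dt_save_ps,
                 duration_ps = meta$duration_ps,
                 cfg = list(seed = meta$seed, config_hash = meta$config_hash),
                 n_retries = NA_integer_),
            class = "sop_trajectory")
}

#' Write a conformation as a PDB snapshot
#'
#' BB beads as CA records, SC beads as CB records, for visualisation.
#'
#' @param conf coordinate matrix.
#' @param topo matching `sop_topology`.
#' @param path output PDB path.
#' @return invisibly, the path.
#' @export
write_conformation_pdb <- function(conf, topo, path) {
  b <- topo$beads
  bio3d::write.pdb(file = path, xyz = as.vector(t(conf)),
                   type = rep("ATOM", nrow(b)),
                   resno = b$res, resid = rep("ALA", nrow(b)),
                   elety = ifelse(b$site == "BB", "CA", "CB"),
                   chain = rep(LETTERS[b$chain], length.out = nrow(b)))
  invisible(path)
}

#' Hash a configuration object
#'
#' Canonical serialisation (sorted keys, fixed precision) written to a
#' temporary file and digested with MD5; embedded in run manifests so any
#' artifact names the exact configuration that produced it.
#'
#' @param cfg any list-like configuration.
#' @return hex MD5 string.
#' @export
config_hash <- function(cfg) {
  cfg <- cfg[order(names(unlist(cfg)))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 12,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.known_config_keys <- c("sequence", "n_steps", "dt", "temperature", "eta",
                        "a_h", "hydrodynamics", "save_stride", "seed",
                        "chi_c", "d", "lag", "k_range", "separation",
                        "stiffness", "n_hmm_states", "forcefield_dir")

#' Load and validate a declarative run configuration
#'
#' One flat YAML document holding the simulation and analysis settings;
#' unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file, or a named list.
#' @return the configuration list with attribute `"hash"`.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Write a reproducibility manifest
#'
#' Inputs, configuration hash, seed and package version, sufficient to re-run
#' a stage bit-for-bit.
#'
#' @param dir output directory.
#' @param inputs named list/character of input descriptions.
#' @param cfg configuration object.
#' @param seed seed used.
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(dir, inputs, cfg, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    inputs = inputs, config_hash = config_hash(cfg), seed = seed,
    package_version = as.character(utils::packageVersion("idpscape")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
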