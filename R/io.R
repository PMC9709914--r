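#' Load a configuration ensemble from structure files
#'
#' Reads a PDB topology (optionally multi-model) and, if given, a DCD or
#' multi-model PDB trajectory, applies an atom selection, and returns the
#' selected coordinates in nanometres (PDB/DCD coordinates are in angstrom
#' and are converted on read). XTC is not supported; convert to DCD first.
#'
#' @param topology path to a PDB file.
#' @param trajectory optional path to a DCD file or a multi-model PDB; when
#'   omitted, the models of `topology` itself form the trajectory.
#' @param residues optional inclusive residue-number range, e.g. `c(2, 11)`
#'   or a vector of residue numbers.
#' @param atoms optional atom names to keep, e.g.
#'   `c("N", "H", "CA", "C", "O")`.
#' @return A [conf_ensemble()] in nm with `atom_labels` (`resno`, `elety`)
#'   from the topology; frame order is preserved.
#' @export
load_ensemble <- function(topology, trajectory = NULL, residues = NULL,
                          atoms = NULL) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  pdb <- bio3d::read.pdb(topology, multi = TRUE)
  sel <- select_topology_atoms(pdb, residues, atoms)

  if (is.null(trajectory)) {
    xyz <- pdb$xyz
  } else {
    if (!file.exists(trajectory)) stop("trajectory file not found: ",
                                       trajectory)
    ext <- tolower(tools::file_ext(trajectory))
    xyz <- switch(ext,
      dcd = bio3d::read.dcd(trajectory, verbose = FALSE),
      pdb = bio3d::read.pdb(trajectory, multi = TRUE)$xyz,
      xtc = stop("XTC trajectories are not supported; convert to DCD ",
                 "(e.g. with 'mdconvert' or 'catdcd') or supply a ",
                 "multi-model PDB"),
      stop("unsupported trajectory format: .", ext,
           " (supported: .dcd, .pdb)"))
  }
  xyz <- as.matrix(xyz)
  n_top_atoms <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * n_top_atoms)
    stop("trajectory has ", ncol(xyz) / 3, " atoms per frame but the ",
         "topology has ", n_top_atoms)
  coords_nm <- xyz[, sel$xyz_idx, drop = FALSE] / 10
  conf_ensemble(coords_nm, n_atoms = length(sel$atom_idx),
                atom_labels = sel$labels)
}

# Resolve a residue-range + atom-name selection against a bio3d pdb object.
select_topology_atoms <- function(pdb, residues, atoms) {
  tab <- pdb$atom
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(residues)) {
    if (length(residues) == 2L) residues <- seq(residues[1L], residues[2L])
    keep <- keep & tab$resno %in% residues
  }
  if (!is.null(atoms)) {
    missing <- setdiff(atoms, unique(tab$elety[keep]))
    if (length(missing) == length(atoms))
      stop("selection matches no atoms; missing atom names: ",
           paste(missing, collapse = ", "))
    if (length(missing))
      warning("atom names not present in the selected residues: ",
              paste(missing, collapse = ", "))
    keep <- keep & tab$elety %in% atoms
  }
  atom_idx <- which(keep)
  if (length(atom_idx) == 0L)
    stop("selection matches no atoms (residues: ",
         if (is.null(residues)) "all" else paste(range(residues),
                                                 collapse = "-"),
         "; atoms: ",
         if (is.null(atoms)) "all" else paste(atoms, collapse = ","), ")")
  xyz_idx <- as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L,
                             3L * atom_idx))
  list(atom_idx = atom_idx, xyz_idx = xyz_idx,
       labels = data.frame(resno = tab$resno[atom_idx],
                           elety = tab$elety[atom_idx]))
}

matrix_cache_header <- function(matrix, selection) {
  c(sprintf("N=%d n_atoms=%d mode=%s", nrow(matrix),
            attr(matrix, "n_atoms"), attr(matrix, "mode")),
    sprintf("selection=%s", selection))
}

#' Write an RMSD matrix cache
#'
#' Stores the upper triangle of a symmetric RMSD matrix together with a
#' header recording N, the atom count, the matrix mode and the selection
#' string. Two variants: a human-readable text format (`# `-prefixed header
#' lines, then one row of the upper triangle per line at full double
#' precision) and a compact binary format (magic `RMSDCLUSTB1`, the same
#' header, then little-endian doubles) whose round-trip is bit-exact.
#'
#' @param matrix an [rmsd_matrix()].
#' @param path output file path.
#' @param format `"binary"` (default) or `"text"`.
#' @param selection free-text selection description stored in the header.
#' @return `path`, invisibly.
#' @export
write_rmsd_matrix <- function(matrix, path, format = c("binary", "text"),
                              selection = "") {
  format <- match.arg(format)
  header <- matrix_cache_header(matrix, selection)
  n <- nrow(matrix)
  upper <- matrix[upper.tri(matrix)]
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#RMSDCLUST matrix v1", paste0("#", header)), con)
    for (i in seq_len(n - 1L)) {
      row <- matrix[i, seq.int(i + 1L, n)]
      writeLines(paste(sprintf("%.17g", row), collapse = " "), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("RMSDCLUSTB1", header), con)
    writeBin(as.numeric(upper), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read an RMSD matrix cache
#'
#' Reads either variant written by [write_rmsd_matrix()], reconstructing
#' the full symmetric matrix, its mode and atom count.
#'
#' @param path cache file path.
#' @return An [rmsd_matrix()] with attribute `selection` from the header.
#' @export
read_rmsd_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix cache not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  binary <- identical(magic, "RMSDCLUSTB1")
  if (!binary && !identical(magic, "#RMSDCLUST matrix v1"))
    stop("not an rmsdclust matrix cache: ", path)
  meta_line <- readLines(con, n = 1L)
  sel_line <- readLines(con, n = 1L)
  meta <- parse_cache_meta(sub("^#", "", meta_line))
  selection <- sub("^#?selection=", "", sel_line)
  n <- meta$N
  n_up <- (n * (n - 1L)) %/% 2L
  upper <- if (binary) {
    readBin(con, "numeric", n = n_up, size = 8L, endian = "little")
  } else {
    as.numeric(scan(con, what = double(), quiet = TRUE))
  }
  if (length(upper) != n_up)
    stop("matrix cache is truncated: expected ", n_up, " values, got ",
         length(upper))
  values <- matrix(0, n, n)
  if (binary) {
    # binary stores upper.tri() order (column-wise)
    values[upper.tri(values)] <- upper
  } else {
    # text stores one row of the upper triangle per line (row-wise)
    pos <- 1L
    for (i in seq_len(n - 1L)) {
      cnt <- n - i
      values[i, seq.int(i + 1L, n)] <- upper[pos:(pos + cnt - 1L)]
      pos <- pos + cnt
    }
  }
  values <- values + t(values)
  out <- rmsd_matrix(values, mode = meta$mode, n_atoms = meta$n_atoms)
  attr(out, "selection") <- selection
  out
}

parse_cache_meta <- function(line) {
  kv <- strsplit(strsplit(trimws(line), "\\s+")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  list(N = as.integer(vals[["N"]]), n_atoms = as.integer(vals[["n_atoms"]]),
       mode = vals[["mode"]])
}

#' Run the full clustering pipeline
#'
#' Orchestrates load -> RMSD matrix (with optional cache reuse) -> cluster
#' -> diagnostics, writing an assignment table, a cluster summary, a
#' coverage table, per-seed profile tables for the top clusters, and a run
#' log, all as TSV/text under `out_dir`. The run is a pure function of the
#' inputs and configuration: rerunning with the same inputs reproduces the
#' outputs bit for bit.
#'
#' @param config a list with entries:
#'   * `ensemble` (a [conf_ensemble()]) **or** `topology`/`trajectory`/
#'     `residues`/`atoms` as for [load_ensemble()];
#'   * `algorithm` (`"rtc"` or `"qtc"`), `threshold` (nm), `min_size`
#'     (default 1);
#'   * `mode` (`"pairwise_fit"` default, or `"prealigned"`);
#'   * `out_dir` (created if missing);
#'   * optional `matrix_cache` (path; reused when its header matches,
#'     recomputed with a warning otherwise), `n_profiles` (default 3),
#'     `size_cutoffs` (default `c(10, 100)`), `bin_width` (default 0.005).
#' @return Invisibly, a list with `ensemble`, `matrix`, `result`,
#'   `coverage` and the output paths.
#' @export
run_pipeline <- function(config) {
  required <- c("algorithm", "threshold", "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  algorithm <- match.arg(tolower(config$algorithm), c("rtc", "qtc"))
  kind <- if (algorithm == "rtc") "radial" else "diametral"
  mode <- if (is.null(config$mode)) "pairwise_fit" else config$mode
  min_size <- if (is.null(config$min_size)) 1L else as.integer(config$min_size)
  n_profiles <- if (is.null(config$n_profiles)) 3L else config$n_profiles
  cutoffs <- if (is.null(config$size_cutoffs)) c(10L, 100L)
             else config$size_cutoffs
  bin_width <- if (is.null(config$bin_width)) 0.005 else config$bin_width
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ensemble <- if (!is.null(config$ensemble)) config$ensemble
  else load_ensemble(config$topology, config$trajectory,
                     config$residues, config$atoms)
  selection <- paste0(
    "residues=", if (is.null(config$residues)) "all"
                 else paste(config$residues, collapse = "-"),
    " atoms=", if (is.null(config$atoms)) "all"
               else paste(config$atoms, collapse = ","))

  mat <- NULL
  cache <- config$matrix_cache
  if (!is.null(cache) && file.exists(cache)) {
    cached <- tryCatch(read_rmsd_matrix(cache), error = function(e) NULL)
    if (!is.null(cached) && nrow(cached) == n_frames(ensemble) &&
        identical(attr(cached, "mode"), mode) &&
        identical(attr(cached, "selection"), selection)) {
      mat <- cached
    } else {
      warning("matrix cache does not match the inputs; recomputing")
    }
  }
  if (is.null(mat)) {
    mat <- pairwise_rmsd_matrix(ensemble, mode = mode)
    if (!is.null(cache))
      write_rmsd_matrix(mat, cache, format = "binary", selection = selection)
  }

  result <- cluster_rmsd(mat, config$threshold, kind, min_size)
  paths <- list(
    assignments = file.path(config$out_dir, "assignments.tsv"),
    summary = file.path(config$out_dir, "cluster_summary.tsv"),
    coverage = file.path(config$out_dir, "coverage.tsv"),
    log = file.path(config$out_dir, "run_log.txt"))
  write_assignments(result, paths$assignments)
  write_cluster_summary(result, mat, paths$summary)
  coverage <- coverage_report(result, cutoffs)
  write_tsv_with_header(coverage, paths$coverage,
                        sprintf("total_clusters=%d",
                                attr(coverage, "total_clusters")))

  top <- utils::head(result$clusters, n_profiles)
  profile_paths <- character(0)
  if (n_frames(ensemble) >= 2L) {
    for (cl in top) {
      p <- seed_profile(mat, cl$seed, bin_width)
      pp <- file.path(config$out_dir,
                      sprintf("profile_seed%04d.tsv", cl$seed))
      write_tsv_with_header(
        data.frame(bin_left = p$breaks[-length(p$breaks)],
                   bin_right = p$breaks[-1], density = p$density),
        pp, sprintf("seed=%d bin_width=%g", cl$seed, bin_width))
      profile_paths <- c(profile_paths, pp)
    }
  }

  digests <- character(0)
  for (f in c(config$topology, config$trajectory))
    if (!is.null(f)) digests <- c(digests, sprintf("%s md5=%s", f,
                                                   tools::md5sum(f)))
  writeLines(c(
    sprintf("rmsdclust %s", as.character(utils::packageVersion("rmsdclust"))),
    sprintf("R %s", R.version.string),
    sprintf("algorithm=%s threshold=%g min_size=%d mode=%s", algorithm,
            config$threshold, min_size, mode),
    sprintf("selection: %s", selection),
    sprintf("frames=%d atoms=%d", n_frames(ensemble), ensemble$n_atoms),
    digests), paths$log)

  invisible(list(ensemble = ensemble, matrix = mat, result = result,
                 coverage = coverage,
                 paths = c(paths, list(profiles = profile_paths))))
}

#' Reproduce the tau-polypeptide clustering benchmark
#'
#' End-to-end harness for the 6001-frame tau-polypeptide trajectory
#' (backbone N, H, CA, C, O atoms of residues 2-11; 50 atoms): builds the
#' pairwise RMSD matrix and runs radial clustering at 0.12 and 0.17 nm and
#' diametral clustering at 0.20 and 0.25 nm (all with `min_size = 1`),
#' reporting total cluster counts, first-cluster diameters and coverage at
#' the 10- and 100-member cutoffs.
#'
#' @param pdb_path path to the reference PDB topology.
#' @param dcd_path path to the DCD trajectory.
#' @param mode matrix mode; the distributed trajectory is pre-aligned, so
#'   both `"pairwise_fit"` (default) and `"prealigned"` are meaningful.
#' @param rtc_thresholds,qtc_thresholds threshold sets in nm.
#' @return List with the ensemble dimensions, and per run: algorithm,
#'   threshold, total cluster count, first-cluster size and diameter, and
#'   the coverage table.
#' @export
reproduce_tau <- function(pdb_path, dcd_path, mode = "pairwise_fit",
                          rtc_thresholds = c(0.12, 0.17),
                          qtc_thresholds = c(0.20, 0.25)) {
  ensemble <- load_ensemble(pdb_path, dcd_path, residues = c(2L, 11L),
                            atoms = c("N", "H", "CA", "C", "O"))
  if (ensemble$n_atoms != 50L)
    warning("expected 50 selected atoms, got ", ensemble$n_atoms)
  mat <- pairwise_rmsd_matrix(ensemble, mode = mode)
  one_run <- function(th, kind) {
    res <- cluster_rmsd(mat, th, kind, min_size = 1L)
    list(algorithm = res$algorithm, threshold = th,
         n_clusters = length(res$clusters),
         c1_size = cluster_sizes(res)[1L],
         c1_diameter = cluster_diameter(mat, res$clusters[[1L]]),
         coverage = coverage_report(res, c(10L, 100L)))
  }
  runs <- c(lapply(rtc_thresholds, one_run, kind = "radial"),
            lapply(qtc_thresholds, one_run, kind = "diametral"))
  list(n_frames = n_frames(ensemble), n_atoms = ensemble$n_atoms,
       mode = mode, runs = runs)
}
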