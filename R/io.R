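# File formats: extended XYZ trajectories, PDB reading, JSON run manifests.

#' Write / read a trajectory as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying the time
#' (`time_ns=<t>`), then `element x y z` records.  Elements are taken from
#' the bead `role` (first letter, uppercased) unless an `elements` vector
#' is supplied.
#'
#' @param trajectory a `dmd_trajectory`
#' @param path output file
#' @param beads optional bead table (for element symbols)
#' @param elements optional explicit element symbols
#' @return `write_xyz` returns `path` invisibly; `read_xyz` returns a list
#'   with `times` and `frames`
#' @export
write_xyz <- function(trajectory, path, beads = NULL, elements = NULL) {
  frames <- trajectory$frames
  if (is.null(frames)) stop("trajectory holds no frames")
  n <- nrow(frames[[1]])
  if (is.null(elements)) {
    elements <- if (!is.null(beads)) toupper(substr(beads$role, 1, 1))
                else rep("C", n)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    writeLines(c(as.character(n),
                 sprintf("time_ns=%.9g", trajectory$times[f])), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", elements,
                       frames[[f]][, 1], frames[[f]][, 2],
                       frames[[f]][, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  times <- numeric(); frames <- list(); i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cm <- lines[i + 1L]
    t <- as.numeric(sub(".*time_ns=([-0-9.eE+]+).*", "\\1", cm))
    block <- lines[i + 1L + seq_len(n)]
    xyz <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
    times <- c(times, t)
    frames <- c(frames, list(xyz))
    i <- i + 2L + n
  }
  list(times = times, frames = frames)
}

#' Read a PDB structure
#'
#' Parses standard fixed-column ATOM/HETATM records (via bio3d), keeping
#' the first alternate location, skipping waters, preserving 1-based
#' author residue numbering, and surfacing calcium HETATM records as ion
#' markers.
#'
#' @param pdb a file path, a single string containing PDB text, or a
#'   character vector of lines
#' @return list: `atoms` (data.frame chain, resno, resid, elety, x, y, z),
#'   `calcium` (coordinates of Ca2+ ion markers)
#' @export
read_pdb <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1]) ||
      grepl("^(ATOM|HETATM|HEADER|REMARK|CRYST)", pdb[1])) {
    lines <- if (length(pdb) > 1L) pdb else strsplit(pdb, "\n")[[1]]
    bad <- which(grepl("^(ATOM|HETATM)", lines) & nchar(lines) < 54)
    if (length(bad))
      stop("malformed fixed-width PDB record(s) at line(s): ",
           paste(head(bad, 5), collapse = ", "))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(lines, path)
  } else if (!file.exists(path)) {
    stop("PDB input is neither parseable text nor an existing file: ", path)
  }
  pd <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pd$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]   # first altloc only
  at <- at[!(at$resid %in% c("HOH", "WAT")), ]         # skip waters
  ca_ion <- at$type == "HETATM" &
    (at$resid %in% c("CA", "CA2") | toupper(trimws(at$elesy)) == "CA")
  calcium <- at[ca_ion, c("chain", "resno", "x", "y", "z")]
  atoms <- at[at$type == "ATOM", c("chain", "resno", "resid", "elety",
                                   "x", "y", "z")]
  rownames(atoms) <- NULL
  list(atoms = atoms, calcium = calcium)
}

#' Write a synthetic two-chain dimer PDB fixture
#'
#' Generates (in code, no external data) a synthetic PDB text emulating an
#' EC1 s-dimer: two 100-residue chains with CA/CB (plus N/C for the
#' glycine-free backbone) arranged as helical domains whose residue
#' 88-to-98 vectors are orthogonal, acidic residues at the calcium
#' coordination positions (Glu11, Asp62, Glu64, Asp96, Asp99), and chain
#' B's N-terminal strand adjacent to chain A's.  This is a synthetic
#' stand-in geometry, not a deposited structure.
#'
#' @param n_res residues per chain
#' @return character vector of PDB lines
#' @export
synthetic_dimer_pdb <- function(n_res = 100) {
  resnames <- rep("ALA", n_res)
  resnames[c(11, 64)] <- "GLU"
  resnames[c(62, 96, 99)] <- "ASP"
  resnames[c(30, 40, 50, 77, 80)] <- c("ARG", "LYS", "ARG", "LYS", "ARG")
  # helical body; residues 85+ run as a straight strand along the chain
  # axis so the 88->98 dimer-angle vector is exactly axial
  hel <- function(i, phase = 0) {
    th <- pmin(i, 84) * 100 * pi / 180 + phase
    cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
  }
  i <- seq_len(n_res)
  bbA <- hel(i)
  # chain B: axis rotated 90 degrees (z -> x), N-terminus near chain A's
  bbB0 <- hel(i, phase = 1)
  bbB <- cbind(bbB0[, 3], bbB0[, 2] + 12, bbB0[, 1])
  mk_chain <- function(bb, ch, serial0) {
    axis_dir <- if (ch == "A") c(0, 0, 1) else c(1, 0, 0)
    lines <- character(0); serial <- serial0
    for (r in i) {
      ca <- bb[r, ]
      radial <- ca - sum(ca * axis_dir) * axis_dir
      radial <- if (sqrt(sum(radial^2)) > 0) radial / sqrt(sum(radial^2))
                else c(1, 0, 0)
      cb <- ca + 1.53 * radial
      npos <- ca + c(-0.5, 1.2, -0.8)
      cpos <- ca + c(0.6, -1.1, 0.9)
      for (atom in list(c("N", npos), c("CA", ca), c("C", cpos),
                        c("CB", cb))) {
        xyz <- as.numeric(atom[2:4])
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, atom[[1]], resnames[r], ch, r, xyz[1], xyz[2], xyz[3],
          substr(atom[[1]], 1, 1)))
        serial <- serial + 1L
      }
    }
    list(lines = lines, serial = serial)
  }
  a <- mk_chain(bbA, "A", 1L)
  b <- mk_chain(bbB, "B", a$serial)
  c("HEADER    SYNTHETIC CADHERIN S-DIMER FIXTURE", a$lines, b$lines, "END")
}

#' Run manifest
#'
#' A JSON-serializable record of a run: configuration snapshot, seeds,
#' package version, output paths and wall time — sufficient to re-run
#' bit-exactly.
#'
#' @param config named list of parameters
#' @param seeds integer seeds used
#' @param outputs named list/vector of output file paths
#' @param wall_time_s elapsed seconds
#' @return class `run_manifest`
#' @export
run_manifest <- function(config, seeds, outputs = list(), wall_time_s = NA) {
  structure(list(package = "cgdmd",
                 version = as.character(packageVersion("cgdmd")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = config, seeds = seeds, outputs = outputs,
                 wall_time_s = wall_time_s),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`
#' @param path JSON output path
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}

#' Write tabular results as TSV with a comment header
#'
#' @param x data.frame
#' @param path output path
#' @param comments character vector of header comment lines
#' @return `path`, invisibly
#' @export
write_tsv_table <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
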