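# Readers, writers, run configuration and packaged reference data.

TRAJECTORY_SCHEMA_VERSION <- 1L

#' Load a SMILES list file
#'
#' One SMILES per line, optionally followed by a whitespace-separated name;
#' blank lines and lines starting with '#' are skipped.  Any unparseable or
#' unsanitizable record raises an error naming the line.
#'
#' @param path file path (.smi)
#' @return named list of \linkS4class{Compound}s
#' @export
loadSmilesList <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[ \t]+")[[1]]
    cp <- tryCatch(parseSmiles(parts[1]), error = function(e)
      stop(sprintf("line %d: invalid SMILES '%s'", i, parts[1]), call. = FALSE))
    nm <- if (length(parts) > 1L) parts[2] else parts[1]
    out[[nm]] <- cp
  }
  out
}

#' Load seed molecules from an SDF file
#'
#' @param path SDF file
#' @param first if TRUE (default) return only the first record
#' @return a \linkS4class{Compound} (or list of them)
#' @export
loadSdf <- function(path, first = TRUE) {
  sdf <- ChemmineR::read.SDFset(path)
  smis <- ChemmineR::sdf2smiles(sdf)
  smis <- as.character(smis)
  cps <- lapply(smis, parseSmiles)
  if (first) cps[[1]] else cps
}

#' Load a protein sequence from FASTA
#'
#' Returns the first record's sequence, validated against the 20-letter
#' amino-acid alphabet plus X; a file with several records uses the first
#' and warns.
#'
#' @param path FASTA file
#' @return protein sequence string
#' @export
loadFastaSequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("no FASTA records in ", path)
  if (length(seqs) > 1L)
    warning("multiple FASTA records; using the first (", names(seqs)[1], ")")
  s <- as.character(seqs[[1]])
  if (!nzchar(s)) stop("empty sequence in ", path)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", s))
    stop("sequence contains letters outside the amino-acid alphabet")
  s
}

#' Write / read a trajectory
#'
#' Writes one JSON record per proposed step (trajectory.jsonl) plus a CSV
#' mirror (trajectory.csv); a schema version is stamped and checked on read.
#'
#' @param trajectory a trajectory data frame
#' @param dir output directory (created if needed)
#' @return (invisibly) the directory
#' @export
writeTrajectory <- function(trajectory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = TRAJECTORY_SCHEMA_VERSION,
               n_records = nrow(trajectory))
  con <- file(file.path(dir, "trajectory.jsonl"), "w")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), con)
  if (nrow(trajectory))
    for (i in seq_len(nrow(trajectory)))
      writeLines(jsonlite::toJSON(as.list(trajectory[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
  close(con)
  utils::write.csv(trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(dir) {
  path <- file.path(dir, "trajectory.jsonl")
  if (!file.exists(path)) stop("no trajectory.jsonl under ", dir)
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  if (is.null(meta$schema_version) ||
      meta$schema_version != TRAJECTORY_SCHEMA_VERSION)
    stop("unsupported trajectory schema version")
  if (length(lines) == 1L)
    return(data.frame(step = integer(0), smiles = character(0),
                      move_kind = character(0), score = numeric(0),
                      accepted = logical(0), is_reset = logical(0)))
  recs <- lapply(lines[-1], function(ln) {
    x <- jsonlite::fromJSON(ln)
    x$score <- if (is.null(x$score)) NA_real_ else as.numeric(x$score)
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Run configuration files
#'
#' YAML round-trip of a run configuration; unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param config a named list of configuration values
#' @param path YAML file path
#' @return \code{readRunConfig}: the validated configuration list
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

RUNCONFIG_KEYS <- c("mode", "target_smiles", "start_smiles", "protein_fasta",
                    "backend", "beta", "n_steps", "reset_interval",
                    "replicas", "stage1_steps", "sync_every", "stage2_steps",
                    "p_add", "fragment_library", "move_probabilities",
                    "seed", "out_dir")

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), RUNCONFIG_KEYS)
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  if (!is.null(cfg$move_probabilities)) {
    p <- unlist(cfg$move_probabilities)
    if (abs(sum(p) - 1) > 1e-9) stop("move probabilities must sum to 1")
  }
  cfg
}

#' Fragment library files
#'
#' One fragment SMILES (with bracketed numeric attachment labels, e.g.
#' \code{[5*]}) per line; the loader validates that every dummy carries a
#' known BRICS label.
#'
#' @param path library file
#' @return a \linkS4class{FragmentLibrary}
#' @export
loadFragmentLibrary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  frags <- lapply(seq_along(lines), function(i) {
    mg <- tryCatch(parse_smiles_mg(lines[i]), error = function(e)
      stop(sprintf("line %d: invalid fragment SMILES '%s'", i, lines[i]),
           call. = FALSE))
    labs <- mg$label[mg$elem == "*"]
    if (any(labs < 1L | labs > 16L))
      stop(sprintf("line %d: attachment label outside 1..16", i), call. = FALSE)
    mg
  })
  new("FragmentLibrary", fragments = frags,
      smiles = vapply(frags, mg_write_smiles, character(1)))
}

#' @rdname loadFragmentLibrary
#' @param library a \linkS4class{FragmentLibrary}
#' @export
writeFragmentLibrary <- function(library, path) {
  writeLines(vapply(library@fragments, mg_write_smiles, character(1)), path)
  invisible(path)
}

#' Packaged 50-fragment library
#'
#' A synthetic stand-in for a random database draw: 50 BRICS fragments
#' derived from the packaged reference ligand SMILES, shipped so the
#' fragment protocol runs with no external database.
#'
#' @return a \linkS4class{FragmentLibrary}
#' @export
defaultFragmentLibrary <- function() {
  path <- system.file("extdata", "fragment_library_synthetic.smi",
                      package = "molmc")
  if (!nzchar(path) || !file.exists(path))
    path <- file.path("inst", "extdata", "fragment_library_synthetic.smi")
  loadFragmentLibrary(path)
}

ref_table <- function(fname) {
  path <- system.file("extdata", fname, package = "molmc")
  if (!nzchar(path) || !file.exists(path))
    path <- file.path("inst", "extdata", fname)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged reference tables
#'
#' \code{recoveryBenchmark}: the ligand-recovery benchmark (PDB code, target
#' SMILES, reported closest compound and dice score).
#' \code{designReference}: design-run reference rows (composite score and
#' its printed components), used to calibrate the ESOL normalization.
#' \code{knownLigands}: known ligands of the four study proteins.
#'
#' @return a data frame
#' @export
recoveryBenchmark <- function() ref_table("recovery_benchmark_ligands.tsv")

#' @rdname recoveryBenchmark
#' @export
designReference <- function() ref_table("design_reference_scores.tsv")

#' @rdname recoveryBenchmark
#' @export
knownLigands <- function() ref_table("known_ligands.tsv")
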