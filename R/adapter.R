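# External-engine adapter: drives a LAMMPS-compatible minimizer through
# files (data file in, log out) instead of the embedded force field.  Never
# required by the rest of the package; the embedded models do not use it.

#' Write a LAMMPS minimization script
#'
#' Emits an input script that reads a data file, applies caller-supplied
#' force-field setup lines (`pair_style`/`pair_coeff` or a ReaxFF block)
#' and runs `minimize` with the four stopping parameters of
#' [minimization_settings()].
#'
#' @param data_file path of the data file the script reads.
#' @param forcefield_lines character vector of engine commands defining the
#'   potential.
#' @param settings a [minimization_settings()].
#' @param path output script path.
#' @return `path`, invisibly.
#' @export
write_lammps_minimize_script <- function(data_file, forcefield_lines,
                                         settings = minimization_settings(),
                                         path) {
  writeLines(c(
    "# minimization script (units metal: eV, Angstrom)",
    "units metal",
    "atom_style atomic",
    "boundary s s p",
    sprintf("read_data %s", data_file),
    forcefield_lines,
    "thermo 10",
    "thermo_style custom step pe fnorm",
    sprintf("minimize %g %g %d %d", settings$energy_tol, settings$force_tol,
            settings$max_iterations, settings$max_evaluations),
    "write_dump all custom final.dump id type x y z"
  ), path)
  invisible(path)
}

#' Parse a LAMMPS log for the final potential energy
#'
#' Reads the last thermodynamic table row and the atom count.
#'
#' @param log_lines character vector (log file content).
#' @return list with `total_energy`, `n_atoms`, `per_atom_energy` (mean
#'   value replicated when no per-atom dump is available).
#' @export
parse_lammps_log <- function(log_lines) {
  am <- regmatches(log_lines, regexec("([0-9]+) atoms", log_lines))
  am <- Filter(function(x) length(x) == 2, am)
  if (!length(am)) stop("cannot find atom count in engine log")
  n <- as.integer(am[[1]][2])
  hdr <- grep("\\bPotEng\\b|\\bpe\\b", log_lines, ignore.case = FALSE)
  if (!length(hdr)) stop("cannot find thermo header (PotEng) in engine log")
  cols <- strsplit(trimws(log_lines[hdr[length(hdr)]]), "[[:space:]]+")[[1]]
  pe_col <- which(cols %in% c("PotEng", "pe", "Pe"))[1]
  if (is.na(pe_col)) stop("no potential-energy column in engine log")
  pe <- NA_real_
  for (k in (hdr[length(hdr)] + 1):length(log_lines)) {
    tok <- strsplit(trimws(log_lines[k]), "[[:space:]]+")[[1]]
    if (length(tok) >= pe_col && !is.na(suppressWarnings(as.numeric(tok[1])))) {
      pe <- suppressWarnings(as.numeric(tok[pe_col]))
    } else if (!is.na(pe)) break
  }
  if (is.na(pe)) stop("no thermo data rows in engine log")
  list(total_energy = pe, n_atoms = n,
       per_atom_energy = rep(pe / n, n))
}

#' Run an external LAMMPS-compatible engine
#'
#' Exports the structure as a LAMMPS data file, writes a minimization
#' script honouring `settings`, invokes `engine_command` and parses the
#' resulting log.  This is an adapter contract: any engine that accepts
#' `-in <script> -log <log>` and prints a standard thermo table works; a
#' test stub that copies a canned log is sufficient to validate the
#' plumbing.
#'
#' @param engine_command path/name of the engine executable.
#' @param structure an `atomistic` structure.
#' @param settings a [minimization_settings()].
#' @param forcefield_lines engine commands defining the potential.
#' @param workdir working directory for the exchange files.
#' @return an `energy_report` built from the engine's final state.
#' @export
external_engine_adapter <- function(engine_command, structure,
                                    settings = minimization_settings(),
                                    forcefield_lines = character(0),
                                    workdir = tempfile("engine")) {
  if (Sys.which(engine_command) == "" && !file.exists(engine_command))
    stop("engine not found: '", engine_command, "'")
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  data_file <- file.path(workdir, "structure.data")
  script <- file.path(workdir, "in.minimize")
  logf <- file.path(workdir, "log.engine")
  write_lammps_data(structure, data_file)
  write_lammps_minimize_script(data_file, forcefield_lines, settings, script)
  status <- suppressWarnings(
    system2(engine_command, c("-in", script, "-log", logf),
            stdout = file.path(workdir, "stdout"), stderr = file.path(workdir, "stderr")))
  if (!file.exists(logf))
    stop("engine produced no log; exit status ", status,
         "; stderr: ", paste(readLines(file.path(workdir, "stderr"),
                                       warn = FALSE), collapse = " | "))
  parsed <- tryCatch(parse_lammps_log(readLines(logf, warn = FALSE)),
                     error = function(e)
                       stop("cannot parse engine log at ", logf, ": ",
                            conditionMessage(e)))
  energy_report(total = parsed$total_energy,
                per_atom = parsed$per_atom_energy, forces = NULL,
                converged = NA, iterations = NA_integer_,
                evaluations = NA_integer_)
}
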