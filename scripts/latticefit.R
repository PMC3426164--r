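#!/usr/bin/env Rscript

# Command-line interface for the latticefit package.
#
# Usage:
#   Rscript scripts/latticefit.R fit --input file.pdb [options]
#   Rscript scripts/latticefit.R benchmark --manifest files.txt [options]
#   Rscript scripts/latticefit.R fixtures --out dir [options]
#   Rscript scripts/latticefit.R lattices
#
# Exit codes: 0 success; 2 input not found / unparseable; 3 unsupported
# lattice or input kind; 4 fit failure; 1 other error.

suppressPackageStartupMessages({
  library(optparse)
  library(latticefit)
})

exit_code_for <- function(cond) {
  if (inherits(cond, "latticefit_not_found") ||
      inherits(cond, "latticefit_parse_error") ||
      inherits(cond, "latticefit_empty_structure")) return(2L)
  if (inherits(cond, "latticefit_unsupported_lattice") ||
      inherits(cond, "latticefit_unsupported_input")) return(3L)
  if (inherits(cond, "latticefit_fit_failure")) return(4L)
  1L
}

usage <- function() {
  cat("subcommands: fit | benchmark | fixtures | lattices\n",
      "run with <subcommand> --help for options\n", file = stderr())
}

common_opts <- list(
  make_option("--lattice", default = "fcc",
              help = "lattice: sqr, cub, fcc or 210 [default %default]"),
  make_option("--mode", default = "backbone",
              help = "backbone or side_chain [default %default]"),
  make_option("--strategy", default = "drmsd",
              help = "drmsd or crmsd [default %default]"),
  make_option("--n-keep", dest = "n_keep", type = "integer", default = 1000L,
              help = "beam width [default %default]"),
  make_option("--rot", dest = "r", type = "integer", default = 10L,
              help = "cRMSD strategy: rotation steps per axis [default %default]"),
  make_option("--rot-ref", dest = "r_ref", type = "integer", default = 5L,
              help = "cRMSD strategy: refinement steps per axis [default %default]"),
  make_option("--bond-length", dest = "bond_length", type = "double",
              default = 3.8, help = "bond length in Angstrom [default %default]")
)

# optional key = value configuration file; explicit CLI flags take precedence
# because config values are installed as option defaults before parsing
apply_config_defaults <- function(args, option_list) {
  ci <- which(args == "--config")
  if (!length(ci)) return(option_list)
  path <- args[ci[1] + 1]
  if (is.na(path) || !file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- setNames(lapply(kv, function(x) trimws(x[2])),
                  vapply(kv, function(x) trimws(x[1]), ""))
  for (i in seq_along(option_list)) {
    flag <- sub("^--", "", option_list[[i]]@long_flag)
    if (flag %in% names(cfg)) {
      val <- cfg[[flag]]
      if (option_list[[i]]@type %in% c("integer", "double"))
        val <- as(val, option_list[[i]]@type)
      option_list[[i]]@default <- val
    }
  }
  option_list
}

cmd_fit <- function(args) {
  option_list <- c(list(
      make_option("--input", help = "PDB file (or 4-character identifier)"),
      make_option("--config", default = NULL,
                  help = "optional key = value config file (flags override)"),
      make_option("--chain", default = NULL, help = "chain [default: first]"),
      make_option("--out-prefix", dest = "out_prefix", default = "latticefit_out",
                  help = "output prefix [default %default]"),
      make_option("--conect", action = "store_true", default = FALSE,
                  help = "write CONECT records"),
      make_option("--quiet", action = "store_true", default = FALSE)
    ), common_opts)
  option_list <- apply_config_defaults(args, option_list)
  opts <- parse_args(OptionParser(
    usage = "latticefit.R fit --input <pdb> [options]",
    option_list = option_list), args = args)
  if (is.null(opts$input)) stop("--input is required", call. = FALSE)
  res <- run_fit(opts$input, chain = opts$chain, lattice = opts$lattice,
                 mode = opts$mode, strategy = opts$strategy,
                 n_keep = opts$n_keep, r = opts$r, r_ref = opts$r_ref,
                 bond_length = opts$bond_length,
                 out_prefix = opts$out_prefix, conect = opts$conect,
                 verbose = !opts$quiet)
  ov <- res$summary[res$summary$fragment == "overall", ]
  cat(sprintf("%d residues  dRMSD %.4f A  cRMSD %.4f A\n",
              ov$length, ov$drmsd, ov$crmsd))
}

cmd_benchmark <- function(args) {
  opts <- parse_args(OptionParser(
    usage = "latticefit.R benchmark --manifest <file-with-one-pdb-path-per-line>",
    option_list = c(list(
      make_option("--manifest", help = "text file listing local PDB paths"),
      make_option("--chain", default = NULL),
      make_option("--out-csv", dest = "out_csv", default = "benchmark.csv")
    ), common_opts)), args = args)
  if (is.null(opts$manifest)) stop("--manifest is required", call. = FALSE)
  files <- readLines(opts$manifest)
  files <- files[nzchar(trimws(files))]
  bench <- run_benchmark(files, lattices = opts$lattice, modes = opts$mode,
                         strategy = opts$strategy, n_keep = opts$n_keep,
                         chain = opts$chain, out_csv = opts$out_csv)
  print(bench$summary)
}

cmd_fixtures <- function(args) {
  opts <- parse_args(OptionParser(
    usage = "latticefit.R fixtures --out <dir>",
    option_list = list(
      make_option("--out", default = "fixtures", help = "output directory"),
      make_option("--lattice", default = "fcc"),
      make_option("--mode", default = "backbone"),
      make_option("--length", type = "integer", default = 30L),
      make_option("--sigma", type = "double", default = 0.5),
      make_option("--count", type = "integer", default = 5L),
      make_option("--seed", type = "integer", default = 1L)
    )), args = args)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(opts$out, "manifest.csv")
  rows <- lapply(seq_len(opts$count), function(i) {
    f <- file.path(opts$out, sprintf("fixture_%03d.pdb", i))
    write_fixture_pdb(opts$lattice, opts$length, opts$mode,
                      sigma = opts$sigma, seed = opts$seed + i, file = f)
    data.frame(file = f, lattice = opts$lattice, mode = opts$mode,
               length = opts$length, sigma = opts$sigma,
               seed = opts$seed + i)
  })
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  cat(sprintf("wrote %d fixtures and %s\n", opts$count, manifest))
}

cmd_lattices <- function(args) {
  for (name in lattice_names()) {
    lat <- make_lattice(name)
    alpha <- move_alphabet(lat)
    cat(sprintf("%s: %d neighbours, scale %.2f A\n", name,
                nrow(lat$neighbors), lat$scale))
    for (i in seq_along(alpha)) {
      cat(sprintf("  %s = (%s)\n", alpha[i], names(alpha)[i]))
    }
  }
}

main <- function() {
  argv <- commandArgs(trailingOnly = TRUE)
  if (!length(argv)) { usage(); quit(status = 1L) }
  sub <- argv[1]; rest <- argv[-1]
  handler <- switch(sub, fit = cmd_fit, benchmark = cmd_benchmark,
                    fixtures = cmd_fixtures, lattices = cmd_lattices,
                    NULL)
  if (is.null(handler)) { usage(); quit(status = 1L) }
  tryCatch(handler(rest), latticefit_error = function(e) {
    cat(sprintf("error: %s\n", conditionMessage(e)), file = stderr())
    quit(status = exit_code_for(e))
  }, error = function(e) {
    cat(sprintf("error: %s\n", conditionMessage(e)), file = stderr())
    quit(status = 1L)
  })
  invisible()
}

main()
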