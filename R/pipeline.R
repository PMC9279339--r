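# stage runners wiring the modules together, with run-metadata capture

write_run_manifest <- function(dir, stage, config, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  meta <- list(stage = stage,
               package_version = as.character(utils::packageVersion("surroseq")),
               config = config,
               input_md5 = as.list(tools::md5sum(inputs)))
  yaml::write_yaml(meta, file.path(dir, paste0("run_", stage, ".yaml")))
}

check_files <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("input file not found: ",
                            paste(missing, collapse = ", "))
  invisible(paths)
}

#' Run one pipeline stage
#'
#' Single programmatic entry point behind the command-line tool. Each
#' stage is deterministic given its seed, validates its inputs, writes its
#' outputs into `config$out`, and records a run manifest (package version,
#' effective configuration, input checksums) next to them.
#'
#' Stages and their configuration fields:
#' * `design`: `genome`, `guides`, `max_mm` (4), `seed`, `out`.
#' * `count`: `manifest`, `mock_r1`, `mock_r2`, `cas9_r1`, `cas9_r2`, `out`.
#' * `call`: `counts`, thresholds (see [surro_thresholds()]), `out`.
#' * `context`: `calls`, `manifest`, `background` ("ALL"/"NSOT"),
#'   `mm_range`, `out`.
#' * `annotate`: `calls`, `manifest`, `gff`, `genes` (optional), `out`.
#' * `simulate`: [sim_config()] fields plus `out`.
#'
#' @param stage Stage name.
#' @param config Named list (e.g. from `yaml::read_yaml`); unknown fields
#'   are rejected for threshold names.
#' @return Invisibly, a list of output paths.
#' @export
surro_run <- function(stage, config) {
  stage <- match.arg(stage, c("design", "count", "call", "context",
                              "annotate", "simulate"))
  out <- config$out %||% "."
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  paths <- switch(stage,
    design = {
      check_files(c(config$genome, config$guides))
      guides <- read_guides(config$guides)
      lib <- design_library(config$genome, guides,
                            max_mismatches = config$max_mm %||% 4L,
                            seed = config$seed %||% 1L)
      p <- export_library(lib, out)
      write_run_manifest(out, "design", config, c(config$genome, config$guides))
      p
    },
    count = {
      check_files(c(config$manifest, config$mock_r1, config$cas9_r1))
      manifest <- read_manifest(config$manifest)
      tc <- tabulate_counts(manifest,
                            mock = list(r1 = config$mock_r1, r2 = config$mock_r2),
                            cas9 = list(r1 = config$cas9_r1, r2 = config$cas9_r2))
      p <- file.path(out, "counts.tsv")
      write_tsv(tc$counts, p)
      write_run_manifest(out, "count", config,
                         unlist(config[c("manifest", "mock_r1", "mock_r2",
                                         "cas9_r1", "cas9_r2")]))
      c(counts = p)
    },
    call = {
      check_files(config$counts)
      counts <- read_tsv(config$counts)
      th <- utils::modifyList(surro_thresholds(),
                              config[intersect(names(config),
                                               names(surro_thresholds()))])
      calls <- call_sites(counts, th)
      flags <- enrichment_depletion(counts)
      calls$enrichment_flag <- flags$enrichment_flag[
        match(calls$construct_id, flags$construct_id)]
      p <- file.path(out, "calls.tsv")
      write_calls(calls, p)
      write_run_manifest(out, "call", c(config, th), config$counts)
      c(calls = p)
    },
    context = {
      check_files(c(config$calls, config$manifest))
      calls <- read_tsv(config$calls)
      manifest <- read_manifest(config$manifest)
      keep <- calls$construct_id[is.na(calls$enrichment_flag) |
                                   calls$enrichment_flag == "none"]
      manifest_k <- manifest[manifest$construct_id %in% keep, ]
      calls_k <- calls[calls$construct_id %in% keep, ]
      mm_range <- config$mm_range %||% c(3L, 4L)
      bg_group <- toupper(config$background %||% "ALL")
      sig <- profile_mismatches(manifest_k, calls_k, "Sig", mm_range)
      bg <- profile_mismatches(manifest_k, calls_k, bg_group, mm_range)
      enr <- hypergeom_enrichment(sig, bg)
      prof <- rbind(
        data.frame(group = "Sig", category = "position",
                   name = names(sig$position_counts),
                   count = as.integer(sig$position_counts)),
        data.frame(group = "Sig", category = "type",
                   name = names(sig$type_counts),
                   count = as.integer(sig$type_counts)),
        data.frame(group = bg_group, category = "position",
                   name = names(bg$position_counts),
                   count = as.integer(bg$position_counts)),
        data.frame(group = bg_group, category = "type",
                   name = names(bg$type_counts),
                   count = as.integer(bg$type_counts)))
      p1 <- file.path(out, "profiles.tsv")
      p2 <- file.path(out, "enrichment.tsv")
      write_tsv(prof, p1)
      write_tsv(enr, p2)
      write_run_manifest(out, "context", config, c(config$calls, config$manifest))
      c(profiles = p1, enrichment = p2)
    },
    annotate = {
      check_files(c(config$calls, config$manifest, config$gff))
      calls <- read_tsv(config$calls)
      manifest <- read_manifest(config$manifest)
      sig <- manifest[manifest$construct_id %in%
                        calls$construct_id[calls$call %in% c("LIOT", "HIOT")], ]
      ann <- annotate_sites(sig, config$gff, config$genes)
      p <- file.path(out, "annotation.tsv")
      write_tsv(ann, p)
      write_run_manifest(out, "annotate", config,
                         c(config$calls, config$manifest, config$gff))
      c(annotation = p)
    },
    simulate = {
      cfg <- do.call(sim_config,
                     config[intersect(names(config), names(formals(sim_config)))])
      gg <- simulate_genome_and_guides(cfg)
      fa <- file.path(out, "genome.fasta")
      gseq <- Biostrings::DNAStringSet(gg$genome)
      Biostrings::writeXStringSet(gseq, fa)
      gt <- file.path(out, "guides.tsv")
      write_tsv(gg$guides, gt)
      tt <- file.path(out, "planted_truth.tsv")
      write_tsv(gg$truth, tt)
      lib <- design_library(gg$genome, gg$guides, seed = cfg$seed)
      export_library(lib, out)
      reads <- simulate_reads(lib$manifest, cfg, out)
      write_run_manifest(out, "simulate", config)
      c(genome = fa, guides = gt, planted_truth = tt,
        unlist(reads[c("mock_r1", "mock_r2", "cas9_r1", "cas9_r2")]))
    })
  invisible(paths)
}
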