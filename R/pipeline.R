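#' Pipeline configuration
#'
#' Assembles (and validates) the full set of thresholds and study dimensions
#' used by [runPipeline()]. Every analysis threshold has an explicit default:
#' differential calls at 5 percent FDR and 1.2-fold change, the GC window
#' [0.20, 0.80], network edges at 1 percent FDR and modules at p < 0.01,
#' 10,000 permutations, 30 percent fold-change divergence for region
#' selectivity, a 35-fold enrichment sample dilution and the 3.7
#' carbon-hydrogen bond factor. A config round-trips unchanged through YAML
#' (see [writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param ... named overrides of any default field.
#' @return a named list with class \code{"utrflux_config"}.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        seed = 1L, nGenes = 200L,
        probesPerRegion = c(10L, 4L, 4L), nSubjects = 12L,
        fdr = 0.05, fc = 1.2, gcLow = 0.20, gcHigh = 0.80,
        networkFdr = 0.01, moduleP = 0.01,
        nPermDE = 10000L, nPermEdges = 10000L, nPermModules = 500L,
        divergence = 0.30, minCC = 0.2,
        dilution = 35, bondFactor = 3.7, arVSMOW = 0.00015595,
        studySizes = c(34L, 19L, 47L),
        trueSynthesisRate = 1.37)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    validatePipelineConfig(cfg)
}

#' @rdname pipelineConfig
#' @param cfg a configuration list.
#' @export
validatePipelineConfig <- function(cfg) {
    required <- c("seed", "nGenes", "probesPerRegion", "nSubjects", "fdr",
                  "fc", "gcLow", "gcHigh", "networkFdr", "moduleP",
                  "nPermDE", "nPermEdges", "nPermModules", "divergence",
                  "minCC", "dilution", "bondFactor", "arVSMOW",
                  "studySizes", "trueSynthesisRate")
    miss <- setdiff(required, names(cfg))
    if (length(miss))
        stop("config is missing field(s): ", paste(miss, collapse = ", "))
    if (cfg$fc < 1) stop("config field 'fc' must be >= 1")
    if (cfg$gcLow >= cfg$gcHigh) stop("config GC window is empty")
    structure(cfg, class = "utrflux_config")
}

#' @rdname pipelineConfig
#' @param path file path of a YAML configuration.
#' @export
writePipelineConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path, precision = 15L)
    invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    for (f in c("probesPerRegion", "studySizes"))
        cfg[[f]] <- as.integer(unlist(cfg[[f]]))
    validatePipelineConfig(cfg)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in order -- data simulation, probe preprocessing,
#' region-wise paired differential expression, UTR-pattern classification,
#' cross-cohort growth correlation, co-expression network analysis and the
#' physiology calculators -- writing each stage's outputs as TSV files under
#' \code{outdir} plus a JSON provenance manifest with the configuration and
#' the MD5 checksum of every output file. Reruns with an identical
#' configuration are bit-identical.
#'
#' @param config a [pipelineConfig()] list.
#' @param outdir output directory (created; one subdirectory per stage).
#' @return invisibly, a list with the in-memory stage results and
#'   \code{manifest} (also written to \code{outdir/manifest.json}).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir) {
    config <- validatePipelineConfig(unclass(config))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage_dir <- function(s) {
        d <- file.path(outdir, s)
        dir.create(d, showWarnings = FALSE)
        d
    }
    run_stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    seed <- as.integer(config$seed)

    ## 1 -- simulate
    d1 <- stage_dir("01_simulate")
    sim <- run_stage("simulate", {
        s <- simulateStudy(nGenes = config$nGenes,
                           probesPerRegion = config$probesPerRegion,
                           nSubjects = config$nSubjects, seed = seed)
        writeStudy(s, d1)
        s
    })

    ## 2 -- probe preprocessing
    d2 <- stage_dir("02_probes")
    rs <- run_stage("probes", {
        r <- preprocessProbes(sim$expr, sim$transcriptome,
                              gcLow = config$gcLow, gcHigh = config$gcHigh)
        .writeTSV(attr(r, "cdf"), file.path(d2, "cdf.tsv"))
        .writeTSV(attr(r, "rejectionLog"), file.path(d2, "rejection_log.tsv"))
        sig <- assay(r, "log2signal")
        .writeTSV(data.frame(probe_set_id = rownames(sig), sig,
                             check.names = FALSE),
                  file.path(d2, "region_signal.tsv"))
        r
    })

    ## 3 -- paired differential expression per region
    d3 <- stage_dir("03_de")
    de <- run_stage("de", {
        x <- regionDE(rs, nPerm = config$nPermDE, seed = seed + 10L,
                      fdr = config$fdr, fc = config$fc)
        for (tag in names(x))
            .writeTSV(as.data.frame(deTable(x[[tag]])),
                      file.path(d3, paste0("de_", tag, ".tsv")))
        x
    })

    ## 4 -- UTR pattern classification
    d4 <- stage_dir("04_classify")
    patterns <- run_stage("classify", {
        p <- classifyUTR(de, attr(rs, "cdf"), divergence = config$divergence)
        .writeTSV(as.data.frame(p), file.path(d4, "utr_patterns.tsv"))
        p
    })

    ## 5 -- cross-cohort growth correlation
    d5 <- stage_dir("05_growthcorr")
    core <- run_stage("growthcorr", {
        genes <- names(sim$classes)
        linked <- genes[sim$classes != "null"]
        sgn <- ifelse(sim$classes[linked] == "concordant_down", -1, 1)
        names(sgn) <- linked
        cohorts <- simulateCohorts(genes, linkedGenes = linked,
                                   linkSign = sgn,
                                   studySizes = config$studySizes,
                                   seed = seed + 20L)
        regulated <- unique(unlist(lapply(de, function(r) {
            cdf <- attr(rs, "cdf")
            ps <- calledSets(r)
            cdf$gene_id[match(ps, cdf$probe_set_id)]
        })))
        cc <- suppressWarnings(
            growthCorrelation(cohorts, regulatedGenes = regulated,
                              minCC = config$minCC))
        .writeTSV(as.data.frame(cc), file.path(d5, "core_signature.tsv"))
        cc
    })

    ## 6 -- co-expression network on the full-length difference matrix
    d6 <- stage_dir("06_network")
    net <- run_stage("network", {
        delta_fl <- pairedDifferences(rs)[rowData(rs)$region == "FL", ,
                                          drop = FALSE]
        n <- coexpressionNetwork(t(delta_fl),
                                 nPermEdges = config$nPermEdges,
                                 edgeQ = config$networkFdr,
                                 nPermModules = config$nPermModules,
                                 moduleP = config$moduleP,
                                 seed = seed + 30L)
        .writeTSV(networkEdges(n), file.path(d6, "edges.tsv"))
        mods <- networkModules(n)
        .writeTSV(data.frame(
            node = unlist(mods),
            module = rep(seq_along(mods), lengths(mods)),
            module_p = rep(moduleSignificance(n), lengths(mods)),
            hub = unlist(mods) %in% hubGenes(n)),
            file.path(d6, "modules.tsv"))
        n
    })

    ## 7 -- turnover and physiology
    d7 <- stage_dir("07_turnover")
    physio <- run_stage("turnover", {
        enr <- simulateEnrichment(
            list(trueRate = config$trueSynthesisRate), seed = seed + 40L)
        rate <- recoverSynthesisRate(enr)
        resp <- simulateResponses(nSubjects = config$nSubjects,
                                  seed = seed + 41L)
        cov <- covTriplet(resp$rt, resp$ul)
        .writeTSV(enr$saliva, file.path(d7, "saliva.tsv"))
        .writeTSV(resp, file.path(d7, "responses.tsv"))
        .writeTSV(data.frame(quantity = c("imyops_pct_per_day",
                                          "cov_rt", "cov_ul", "cov_hypat"),
                             value = c(rate, cov)),
                  file.path(d7, "summary.tsv"))
        list(enrichment = enr, rate = rate, responses = resp, cov = cov)
    })

    ## provenance manifest
    cfg_path <- file.path(outdir, "config.yaml")
    writePipelineConfig(config, cfg_path)
    files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    manifest <- list(
        pipeline = "utrflux",
        stages = c("simulate", "probes", "de", "classify", "growthcorr",
                   "network", "turnover"),
        seed = seed,
        config_md5 = unname(tools::md5sum(cfg_path)),
        files = lapply(stats::setNames(
                           files, substring(files, nchar(outdir) + 2L)),
                       function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(sim = sim, regionSignal = rs, de = de,
                   patterns = patterns, core = core, network = net,
                   physiology = physio, manifest = manifest))
}
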