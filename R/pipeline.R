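#' Pipeline configuration
#'
#' A single flat configuration shared by all stages. Defaults mirror the
#' analysis conventions of the case-control design the package implements:
#' significance at adjusted p < 0.05, a blank-ratio threshold of 10, five
#' network modules, fifteen loading clusters, components retained to 90%
#' variance, two PLS-DA latent variables.
#'
#' @param seed master seed for the simulate stage.
#' @param stages character vector of stages to run, in order, from
#'   \code{c("simulate", "preprocess", "edc", "differential", "enrichment",
#'   "network", "multivariate")}.
#' @param blank_ratio_threshold,fdr_alpha,beta,tau,k_modules,
#'   k_loading_clusters,variance_fraction,n_lv,bh_monotone analysis knobs;
#'   see the stage functions.
#' @param n_control,n_case,n_features,fraction_contaminated simulate-stage
#'   sizes.
#' @param out_dir directory for artifacts (created if needed); NULL to skip
#'   writing.
#' @return a validated config list (class \code{"pipelineConfig"}).
#' @export
pipelineConfig <- function(seed = 1,
                           stages = c("simulate", "preprocess", "edc",
                               "differential", "enrichment", "network",
                               "multivariate"),
                           blank_ratio_threshold = 10, fdr_alpha = 0.05,
                           beta = 6, tau = 0.1, k_modules = 5,
                           k_loading_clusters = 15, variance_fraction = 0.90,
                           n_lv = 2, bh_monotone = TRUE,
                           n_control = 19, n_case = 16, n_features = 389,
                           fraction_contaminated = 0.1,
                           out_dir = NULL) {
    cfg <- as.list(environment())
    all_stages <- c("simulate", "preprocess", "edc", "differential",
        "enrichment", "network", "multivariate")
    if (!all(stages %in% all_stages))
        stop("unknown stage(s): ", paste(setdiff(stages, all_stages),
            collapse = ", "), call. = FALSE)
    if (fdr_alpha <= 0 || fdr_alpha >= 1)
        stop("'fdr_alpha' must lie in (0, 1)", call. = FALSE)
    if (blank_ratio_threshold <= 0)
        stop("'blank_ratio_threshold' must be positive", call. = FALSE)
    # stage dependencies, checked before anything runs
    needs <- list(preprocess = "simulate", edc = "simulate",
        differential = "preprocess", enrichment = "differential",
        network = "preprocess", multivariate = "preprocess")
    for (s in stages) {
        miss <- setdiff(needs[[s]], stages)
        if (length(miss))
            stop("stage '", s, "' requires stage(s): ",
                paste(miss, collapse = ", "), call. = FALSE)
    }
    structure(cfg, class = "pipelineConfig")
}

.log_stage <- function(log_lines, fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    c(log_lines, line)
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in order (simulate, preprocess, edc,
#' differential, enrichment, network, multivariate), keeps every
#' intermediate result, optionally writes all artifacts plus a JSON
#' manifest (config, seed, package version, per-stage dimensions) and a
#' plain-text log to \code{config$out_dir}. A stage failure aborts with an
#' error naming the failing stage. Identical config + seed give identical
#' numeric artifacts.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisible list with every stage's results plus \code{manifest}.
#' @examples
#' cfg <- pipelineConfig(seed = 7, n_features = 60, n_control = 6,
#'     n_case = 6, k_loading_clusters = 5)
#' res <- runPipeline(cfg)
#' names(res)
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    res <- list()
    log_lines <- character(0)
    dims <- list()
    run <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                call. = FALSE))
    }
    st <- config$stages

    if ("simulate" %in% st) {
        run("simulate", {
            res$cohort <- generateCohort(config$n_control, config$n_case,
                seed = config$seed)
            sizes <- .default_pathway_sizes(config$n_features)
            sim <- generateMetabolome(res$cohort,
                n_features = config$n_features, pathway_sizes = sizes,
                seed = config$seed)
            res$raw <- sim$table
            res$truth <- sim$truth
            res$blanks <- generateBlankProfile(res$raw,
                config$fraction_contaminated, seed = config$seed)
        })
        dims$simulate <- dim(res$raw)
        log_lines <- .log_stage(log_lines,
            "simulate: %d samples x %d features", dims$simulate[1],
            dims$simulate[2])
    }
    if ("preprocess" %in% st) {
        run("preprocess", {
            pp <- preprocessPipeline(res$raw, res$blanks$blank_means,
                threshold = config$blank_ratio_threshold)
            res$pareto <- pp$table
            res$log_table <- pp$log_table
            res$filter_report <- pp$filter_report
        })
        dims$preprocess <- dim(res$pareto)
        log_lines <- .log_stage(log_lines,
            "preprocess: %d samples x %d features kept (of %d)",
            dims$preprocess[1], dims$preprocess[2], config$n_features)
    }
    if ("edc" %in% st) {
        run("edc", {
            panel <- analytePanel()
            edc <- generateEDC(res$cohort, panel, seed = config$seed)
            meas <- imputeBelowLOQ(edc$measurements, panel)
            meas <- creatinineAdjust(meas, res$cohort)
            res$edc_measurements <- meas
            res$edc_truth <- edc$truth
            res$edc_indices <- molarSums(meas, panel)
        })
        dims$edc <- dim(res$edc_indices)
        log_lines <- .log_stage(log_lines, "edc: %d samples x %d indices",
            dims$edc[1], dims$edc[2] - 1L)
    }
    if ("differential" %in% st) {
        run("differential", {
            res$diff <- differentialAbundance(res$pareto, res$cohort,
                alpha = config$fdr_alpha, monotone = config$bh_monotone)
        })
        dims$differential <- c(nrow(res$diff), sum(res$diff$significant))
        log_lines <- .log_stage(log_lines,
            "differential: %d features tested, %d significant at q < %g",
            nrow(res$diff), sum(res$diff$significant), config$fdr_alpha)
    }
    if ("enrichment" %in% st) {
        run("enrichment", {
            kept <- match(res$diff$feature_id,
                featureIds(res$raw))
            flags <- stats::setNames(res$diff$significant, res$diff$feature_id)
            pw <- stats::setNames(res$truth$pathway_label[kept],
                res$diff$feature_id)
            res$enrichment <- fisherEnrichment(flags, pw,
                monotone = config$bh_monotone)
        })
        dims$enrichment <- nrow(res$enrichment)
        log_lines <- .log_stage(log_lines, "enrichment: %d pathways tested",
            nrow(res$enrichment))
    }
    if ("network" %in% st) {
        run("network", {
            res$network <- buildNetwork(res$pareto, beta = config$beta,
                tau = config$tau)
            labels <- clusterModules(res$network@diss, k = config$k_modules)
            res$modules <- eigenmetabolites(res$pareto, labels)
            res$module_assoc <- moduleOutcomeAssociation(res$modules,
                res$cohort)
        })
        dims$network <- c(nrow(res$network@correlation), config$k_modules)
        log_lines <- .log_stage(log_lines,
            "network: %d features, %d modules", dims$network[1],
            dims$network[2])
    }
    if ("multivariate" %in% st) {
        run("multivariate", {
            res$pca <- runPCA(res$pareto)
            npc <- nComponentsForVariance(res$pca, config$variance_fraction)
            res$n_pcs <- npc
            res$loading_clusters <- clusterLoadings(res$pca, npc,
                k = min(config$k_loading_clusters, ncol(intensities(res$pareto))))
            res$outcome_cor <- featureOutcomeCorrelations(res$pareto,
                res$cohort, res$loading_clusters)
            res$plsda <- runPLSDA(res$pareto, res$cohort, n_lv = config$n_lv)
        })
        dims$multivariate <- c(res$n_pcs, length(unique(res$loading_clusters)))
        log_lines <- .log_stage(log_lines,
            "multivariate: %d PCs reach %.0f%% variance; %d loading clusters; %d PLS-DA LVs",
            res$n_pcs, 100 * config$variance_fraction,
            length(unique(res$loading_clusters)), config$n_lv)
    }

    manifest <- list(
        package_version = as.character(utils::packageVersion("ThyroMetab")),
        seed = config$seed,
        config = unclass(config)[setdiff(names(config), "out_dir")],
        stages_completed = st,
        dimensions = dims
    )
    res$manifest <- manifest
    res$log <- log_lines

    if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        od <- config$out_dir
        writeCohort(res$cohort, file.path(od, "cohort.csv"))
        writeFeatureTable(res$raw, file.path(od, "features_raw.tsv"))
        writeTruth(res$truth, file.path(od, "truth.json"))
        if (!is.null(res$pareto))
            writeFeatureTable(res$pareto, file.path(od, "features_pareto.tsv"))
        if (!is.null(res$filter_report))
            writeResultCSV(res$filter_report, file.path(od, "filter_report.csv"))
        if (!is.null(res$edc_indices))
            writeResultCSV(res$edc_indices, file.path(od, "edc_indices.csv"))
        if (!is.null(res$diff))
            writeResultCSV(res$diff, file.path(od, "differential.csv"))
        if (!is.null(res$enrichment))
            writeResultCSV(res$enrichment, file.path(od, "enrichment.csv"))
        if (!is.null(res$modules)) {
            writeResultCSV(data.frame(
                feature_id = names(moduleLabels(res$modules)),
                module = moduleLabels(res$modules)),
                file.path(od, "modules.csv"))
            writeResultCSV(res$module_assoc,
                file.path(od, "module_associations.csv"))
        }
        if (!is.null(res$plsda))
            writeResultCSV(data.frame(feature_id = names(res$plsda$vip),
                vip = res$plsda$vip), file.path(od, "vip.csv"))
        jsonlite::write_json(manifest, file.path(od, "manifest.json"),
            digits = NA, auto_unbox = TRUE, pretty = TRUE)
        writeLines(log_lines, file.path(od, "pipeline.log"))
    }
    invisible(res)
}

# split n features over nine pathway groups, proportional to the canonical
# 389-feature composition
.default_pathway_sizes <- function(n_features) {
    base <- c(22, 106, 74, 7, 108, 5, 8, 6, 53)
    if (n_features == 389) return(base)
    sz <- floor(base / 389 * n_features)
    sz[sz == 0] <- 1
    rem <- n_features - sum(sz)
    if (rem > 0) {
        ord <- order(-base)
        for (i in seq_len(rem)) sz[ord[(i - 1) %% 9 + 1]] <-
            sz[ord[(i - 1) %% 9 + 1]] + 1
    } else if (rem < 0) {
        for (i in seq_len(-rem)) {
            j <- which.max(sz)
            sz[j] <- sz[j] - 1
        }
    }
    sz
}
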