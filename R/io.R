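#' @include AllClasses.R edges.R
NULL

# full-precision numeric formatting for TSV round trips
fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA"
  )
}

readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

matrixToTsv <- function(m, path, idCol = "sample_id") {
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- idCol
  for (j in colnames(m)) df[[j]] <- fmtNum(m[, j])
  writeTsv(df, path)
}

tsvToMatrix <- function(path, idCol = "sample_id") {
  df <- readTsv(path)
  if (!idCol %in% names(df)) stop(path, " lacks a '", idCol, "' column", call. = FALSE)
  ids <- as.character(df[[idCol]])
  if (anyDuplicated(ids) > 0) {
    stop(
      "duplicate sample id(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(df[setdiff(names(df), idCol)])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a synthetic cohort as plain-text tables
#'
#' One TSV per omic (and per microbiome age), an annotation TSV per
#' annotated omic, and the planted ground truth as JSON. The dialect is the
#' package's own canonical interchange and is exactly inverted by
#' \code{\link{readCohortTables}}.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(name) {
    files <<- c(files, file.path(dir, name))
    file.path(dir, name)
  }
  matrixToTsv(cohort@genotype@mac, put("genotype.tsv"))
  writeTsv(cohort@genotype@snpInfo, put("snp_info.tsv"))
  for (mb in cohort@microbiome) {
    matrixToTsv(mb@counts, put(sprintf("microbiome_age_%s.tsv", mb@age)))
  }
  matrixToTsv(cohort@metabolome@abundance, put("metabolome.tsv"))
  writeTsv(cohort@metabolome@metabInfo, put("metabolite_info.tsv"))
  ph <- cohort@phenotypes
  df <- data.frame(
    sample_id = rownames(ph@percentile),
    race = as.character(ph@covariates$race),
    sex = as.character(ph@covariates$sex),
    site = as.character(ph@covariates$site),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(ph@ages)) {
    df[[paste0("bmi_percentile_", ph@ages[j])]] <- fmtNum(ph@percentile[, j])
    df[[paste0("bmi_category_", ph@ages[j])]] <- fmtNum(ph@category[, j])
  }
  writeTsv(df, put("phenotypes.tsv"))
  jsonlite::write_json(cohort@truth, put("truth.json"), digits = NA, dataframe = "rows")
  invisible(files)
}

#' Read the four omic tables written by \code{writeCohort}
#'
#' Reads the TSV dialect back, validates domains (minor allele counts in
#' \{0,1,2,NA\}, integral non-negative microbiome counts, covariate levels
#' against a declared set when one is given), and aligns all tables on the
#' intersection of the genotype and phenotype sample sets (the always-on
#' tables); per-age omics are restricted to that set. No imputation is ever
#' performed. A load report records per-omic sample counts and dropped ids.
#'
#' @param dir directory written by \code{\link{writeCohort}}.
#' @param covariateLevels optional named list of allowed levels for race,
#'   sex, site; unknown levels are a hard error.
#' @return list with \code{genotype}, \code{microbiome} (named list by age),
#'   \code{metabolome}, \code{phenotypes}, \code{truth} (if present) and
#'   \code{report}.
#' @export
readCohortTables <- function(dir, covariateLevels = NULL) {
  mac <- tsvToMatrix(file.path(dir, "genotype.tsv"))
  bad <- !is.na(mac) & !(mac %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "genotype.tsv: minor allele count out of domain at [%s, %s] (value %s)",
      rownames(mac)[idx[1L]], colnames(mac)[idx[2L]], mac[idx[1L], idx[2L]]
    ), call. = FALSE)
  }
  info <- readTsv(file.path(dir, "snp_info.tsv"))

  ph <- readTsv(file.path(dir, "phenotypes.tsv"))
  if (anyDuplicated(ph$sample_id) > 0) {
    stop("duplicate sample id(s) in phenotypes.tsv", call. = FALSE)
  }
  pcols <- grep("^bmi_percentile_", names(ph), value = TRUE)
  ages <- as.numeric(sub("^bmi_percentile_", "", pcols))
  perc <- as.matrix(ph[pcols])
  catm <- as.matrix(ph[paste0("bmi_category_", ages)])
  storage.mode(perc) <- storage.mode(catm) <- "double"
  rownames(perc) <- rownames(catm) <- ph$sample_id
  colnames(perc) <- colnames(catm) <- as.character(ages)
  covs <- ph[c("race", "sex", "site")]
  rownames(covs) <- ph$sample_id
  if (!is.null(covariateLevels)) {
    for (nm in intersect(names(covariateLevels), names(covs))) {
      unknown <- setdiff(unique(covs[[nm]]), covariateLevels[[nm]])
      if (length(unknown)) {
        stop(
          "unknown ", nm, " level(s) in phenotypes.tsv: ",
          paste(unknown, collapse = ", "),
          call. = FALSE
        )
      }
      covs[[nm]] <- factor(covs[[nm]], levels = covariateLevels[[nm]])
    }
  } else {
    for (nm in names(covs)) covs[[nm]] <- factor(covs[[nm]])
  }

  core <- intersect(rownames(mac), rownames(perc))
  report <- list(
    n_aligned = length(core),
    dropped = list(
      genotype = setdiff(rownames(mac), core),
      phenotypes = setdiff(rownames(perc), core)
    ),
    n_samples = list(genotype = nrow(mac), phenotypes = nrow(perc))
  )

  genotype <- new("GenotypeTable",
    mac = mac[core, , drop = FALSE],
    snpInfo = info
  )
  phenotypes <- new("PhenotypeSeries",
    percentile = perc[core, , drop = FALSE],
    category = catm[core, , drop = FALSE],
    ages = ages, covariates = covs[core, , drop = FALSE]
  )

  mb <- list()
  for (f in sort(list.files(dir, pattern = "^microbiome_age_.*\\.tsv$"))) {
    age <- as.numeric(sub("^microbiome_age_(.*)\\.tsv$", "\\1", f))
    cm <- tsvToMatrix(file.path(dir, f))
    if (anyNA(cm) || any(cm < 0) || any(cm != round(cm))) {
      stop(f, ": microbiome counts must be non-negative integers", call. = FALSE)
    }
    keep <- intersect(rownames(cm), core)
    report$n_samples[[paste0("microbiome_", age)]] <- nrow(cm)
    report$dropped[[paste0("microbiome_", age)]] <- setdiff(rownames(cm), core)
    mb[[as.character(age)]] <- new("MicrobiomeCounts",
      counts = cm[keep, , drop = FALSE], age = age
    )
  }

  ab <- tsvToMatrix(file.path(dir, "metabolome.tsv"))
  minfo <- readTsv(file.path(dir, "metabolite_info.tsv"))
  keep <- intersect(rownames(ab), core)
  report$n_samples$metabolome <- nrow(ab)
  report$dropped$metabolome <- setdiff(rownames(ab), core)
  metabolome <- new("MetaboliteTable",
    abundance = ab[keep, , drop = FALSE],
    metabInfo = minfo
  )

  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath)) {
    df <- as.data.frame(jsonlite::read_json(truthPath, simplifyVector = TRUE))
    if (!nrow(df)) {
      df <- data.frame(
        source_type = character(), source_id = character(),
        target_type = character(), target_id = character(),
        effect_size = numeric(), ages = character(), stringsAsFactors = FALSE
      )
    }
    df
  } else {
    NULL
  }
  list(
    genotype = genotype, microbiome = mb, metabolome = metabolome,
    phenotypes = phenotypes, truth = truth, report = report
  )
}

#' Write an association-edge table as TSV
#'
#' Stable ordering (ascending p, then node ids) for diffability; numeric
#' columns are written with 15 significant digits so a read back preserves
#' slopes and p-values to at least 12 significant digits. An empty edge list
#' produces a header-only file.
#'
#' @param edges edge data.frame (see \code{\link{associationEdges}}).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeEdges <- function(edges, path) {
  validateEdges(edges)
  out <- orderEdges(edges)
  for (j in c("beta", "se", "p", "q")) out[[j]] <- fmtNum(out[[j]])
  writeTsv(out, path)
  invisible(path)
}

#' Read an association-edge table written by \code{writeEdges}
#' @param path TSV file.
#' @return edge data.frame.
#' @export
readEdges <- function(path) {
  df <- readTsv(path)
  stopifnot(all(EDGE_COLUMNS %in% names(df)))
  for (j in c("beta", "se", "p", "q")) df[[j]] <- as.numeric(df[[j]])
  df$n_used <- as.integer(df$n_used)
  df$sign <- as.numeric(df$sign)
  df$age <- as.character(df$age)
  df$tier <- as.character(df$tier)
  validateEdges(df)
  df
}

#' Convert an OmicsNetwork to an igraph graph
#'
#' Vertices carry the omic \code{type}; edges carry \code{sign},
#' \code{beta}, \code{p} and provenance \code{stage}.
#'
#' @param network an \code{\linkS4class{OmicsNetwork}}.
#' @return an undirected \code{igraph} graph.
#' @export
asIgraph <- function(network) {
  stopifnot(is(network, "OmicsNetwork"))
  e <- network@edges
  igraph::graph_from_data_frame(
    d = data.frame(
      from = e$node_a, to = e$node_b, sign = e$sign,
      beta = e$beta, p = e$p, stage = e$stage, age = e$age,
      stringsAsFactors = FALSE
    ),
    directed = FALSE,
    vertices = network@nodes
  )
}

#' Export an OmicsNetwork as GraphML
#' @param network an \code{\linkS4class{OmicsNetwork}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGraphML <- function(network, path) {
  igraph::write_graph(asIgraph(network), path, format = "graphml")
  invisible(path)
}

#' Write detected loops as JSON records
#'
#' One record per loop with its canonical node cycle, omic types, edge
#' signs, sign product and meaningful flag.
#'
#' @param loops loop data.frame from \code{\link{findLoops}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeLoopsJson <- function(loops, path) {
  recs <- lapply(seq_len(nrow(loops)), function(i) {
    list(
      nodes = loops$nodes[[i]], types = loops$types[[i]],
      signs = loops$signs[[i]], sign_product = loops$sign_product[i],
      meaningful = loops$meaningful[i]
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Export genotypes as a minimal VCF (GT only)
#'
#' Site-level VCF with a single GT FORMAT field; the minor allele is written
#' as ALT, so the per-sample ALT dosage equals the minor allele count. The
#' gene symbol is carried in the INFO field as \code{GENE=}.
#'
#' @param genotype a \code{\linkS4class{GenotypeTable}}.
#' @param path output file (uncompressed .vcf).
#' @return invisibly, \code{path}.
#' @export
writeGenotypeVcf <- function(genotype, path) {
  stopifnot(is(genotype, "GenotypeTable"))
  mac <- genotype@mac
  info <- genotype@snpInfo
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", rownames(mac)
    ), collapse = "\t")
  ), con)
  gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(mac))) {
    g <- mac[, j]
    gt <- ifelse(is.na(g), "./.", gtCode[as.character(g)])
    writeLines(paste(c(
      info$chrom[j], info$position[j], info$snp_id[j], "A", "C", ".", "PASS",
      paste0("GENE=", info$gene[j]), "GT", gt
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Import genotypes from a VCF with GT fields
#'
#' The ALT allele is treated as the minor allele only when its sample
#' frequency is at most 0.5; otherwise the dosage is complemented
#' (\code{2 - dosage}) so the stored values are always minor allele counts.
#'
#' @param path VCF file.
#' @return a \code{\linkS4class{GenotypeTable}}; SNPs whose ALT dosage was
#'   complemented are listed in the \code{complemented} attribute.
#' @export
readGenotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(s) {
    if (is.na(s) || s %in% c("./.", ".|.")) {
      return(NA_real_)
    }
    sum(as.numeric(strsplit(s, "[/|]")[[1L]]))
  })
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gene <- sub("^.*GENE=([^;]*).*$", "\\1", fix$INFO)
  gene[!grepl("GENE=", fix$INFO)] <- NA_character_
  complemented <- character()
  for (i in seq_len(nrow(dose))) {
    af <- mean(dose[i, ], na.rm = TRUE) / 2
    if (!is.na(af) && af > 0.5) {
      dose[i, ] <- 2 - dose[i, ]
      complemented <- c(complemented, fix$ID[i])
    }
  }
  mac <- t(dose)
  colnames(mac) <- fix$ID
  out <- new("GenotypeTable",
    mac = mac,
    snpInfo = data.frame(
      snp_id = fix$ID, chrom = fix$CHROM,
      position = as.numeric(fix$POS), gene = gene,
      stringsAsFactors = FALSE
    )
  )
  attr(out, "complemented") <- complemented
  out
}
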