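# Data container, file formats, filtering and pre-mapping QC.
#
# Dosage file dialect: comma-separated, '#' comment lines, three header
# records (ploidy, n.ind, n.mrk), then a header row
# "marker,dP,dQ,<ind1>,..." and one row per marker.  Missing dosages are
# "NA".

#' Dosage dataset for a full-sib population
#'
#' @param markers data frame with columns \code{name}, \code{dP},
#'   \code{dQ} (parental dosages) and optionally \code{chrom},
#'   \code{position}.
#' @param dosages integer matrix, markers x individuals, entries in
#'   \code{0..m} or NA.
#' @param m even ploidy.
#' @param priors optional array \code{(m+1) x n_mrk x n_ind} of
#'   genotype-caller posterior distributions over dosage classes; when
#'   present it overrides hard calls as the HMM emission.
#' @return object of class \code{dosage_data}.
#' @export
dosage_data <- function(markers, dosages, m, priors = NULL) {
  m <- check_ploidy(m)
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(markers),
            all(c("name", "dP", "dQ") %in% names(markers)),
            nrow(markers) == nrow(dosages))
  if (anyDuplicated(markers$name)) {
    stop("duplicated marker names: ",
         paste(unique(markers$name[duplicated(markers$name)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(markers$dP < 0 | markers$dP > m | markers$dQ < 0 | markers$dQ > m)) {
    stop("parental dosages must lie in 0..", m, call. = FALSE)
  }
  markers$dP <- as.integer(markers$dP)
  markers$dQ <- as.integer(markers$dQ)
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > m))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(dosages))
    stop("dosage out of range 0..", m, " at marker ",
         markers$name[rc[1]], ", individual ", rc[2], call. = FALSE)
  }
  if (!is.null(priors)) {
    stopifnot(length(dim(priors)) == 3, dim(priors)[1] == m + 1,
              dim(priors)[2] == nrow(dosages),
              dim(priors)[3] == ncol(dosages))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("Ind%d", seq_len(ncol(dosages)))
  }
  structure(list(markers = markers, dosages = dosages, m = m,
                 n_mrk = nrow(dosages), n_ind = ncol(dosages),
                 priors = priors),
            class = "dosage_data")
}

#' @export
print.dosage_data <- function(x, ...) {
  cat("dosage_data: ploidy", x$m, "|", x$n_mrk, "markers |", x$n_ind,
      "individuals |", sum(is.na(x$dosages)), "missing calls",
      if (!is.null(x$priors)) "| caller priors attached" else "", "\n")
  invisible(x)
}

# Emission prior array (m+1) x z x n for a dataset: caller priors when
# attached, else indicator (or global-error-smoothed) distributions from
# hard calls; missing observations get the polysomic segregation prior.
dataset_priors <- function(dataset, epsilon = 0) {
  m <- dataset$m
  if (!is.null(dataset$priors)) return(dataset$priors)
  z <- dataset$n_mrk; n <- dataset$n_ind
  pri <- array(0, dim = c(m + 1, z, n))
  for (k in seq_len(z)) {
    poly <- polysomic_prior(dataset$markers$dP[k], dataset$markers$dQ[k], m)
    obs <- dataset$dosages[k, ]
    pk <- matrix(0, m + 1, n)
    miss <- is.na(obs)
    if (any(!miss)) {
      if (epsilon > 0) {
        pk[, !miss] <- epsilon / m
        pk[cbind(obs[!miss] + 1L, which(!miss))] <- 1 - epsilon
      } else {
        pk[cbind(obs[!miss] + 1L, which(!miss))] <- 1
      }
    }
    if (any(miss)) pk[, miss] <- poly
    pri[, k, ] <- pk
  }
  pri
}

#' Filter dosage observations impossible under polysomic segregation
#'
#' Sets to missing every offspring observation lying outside the feasible
#' dosage classes implied by the parental dosages (e.g. dosages higher than
#' the two parents can jointly transmit, as produced by double-reduced
#' gametes or miscalls), and reports per-marker counts.
#'
#' @param dataset a \code{\link{dosage_data}}.
#' @return list with \code{dataset} (filtered) and \code{report} (data
#'   frame: marker, n_filtered).
#' @export
filter_impossible_dosages <- function(dataset) {
  m <- dataset$m
  nflt <- integer(dataset$n_mrk)
  for (k in seq_len(dataset$n_mrk)) {
    feas <- feasible_dosage_classes(dataset$markers$dP[k],
                                    dataset$markers$dQ[k], m)
    bad <- !is.na(dataset$dosages[k, ]) & !(dataset$dosages[k, ] %in% feas)
    nflt[k] <- sum(bad)
    dataset$dosages[k, bad] <- NA
  }
  list(dataset = dataset,
       report = data.frame(marker = dataset$markers$name,
                           n_filtered = nflt))
}

#' Per-marker segregation goodness-of-fit
#'
#' Chi-square test of the observed offspring dosage frequencies against the
#' polysomic segregation prior, per marker.  Markers with a single feasible
#' class (or no observed data) pass trivially with p = 1.
#'
#' @param dataset a \code{\link{dosage_data}}.
#' @return data frame: marker, chisq, df, p_value, n_obs.
#' @export
segregation_check <- function(dataset) {
  m <- dataset$m
  out <- lapply(seq_len(dataset$n_mrk), function(k) {
    exp_p <- polysomic_prior(dataset$markers$dP[k], dataset$markers$dQ[k], m)
    obs <- dataset$dosages[k, ]
    obs <- obs[!is.na(obs)]
    classes <- which(exp_p > 0) - 1L
    if (length(classes) <= 1L || length(obs) == 0L) {
      return(data.frame(marker = dataset$markers$name[k], chisq = 0,
                        df = 0L, p_value = 1, n_obs = length(obs)))
    }
    cnt <- vapply(classes, function(d) sum(obs == d), numeric(1))
    expc <- exp_p[classes + 1L] * length(obs)
    stat <- sum((cnt - expc)^2 / expc)
    df <- length(classes) - 1L
    data.frame(marker = dataset$markers$name[k], chisq = stat, df = df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE),
               n_obs = length(obs))
  })
  do.call(rbind, out)
}

format_header <- function(params) {
  c(paste0("# polyphase ",
           as.character(utils::packageVersion("polyphase"))),
    vapply(names(params), function(k) {
      paste0("# param ", k, " = ", paste(params[[k]], collapse = " "))
    }, character(1)))
}

#' Read and write the dosage file format
#'
#' Comma-separated text with \code{#} comment lines, header records
#' \code{ploidy}, \code{n.ind}, \code{n.mrk}, a column header
#' \code{marker,dP,dQ,<individual names>} and one row per marker; missing
#' dosages are \code{NA}.
#'
#' @param path file path.
#' @param dataset a \code{\link{dosage_data}} (for writing).
#' @param params named list of parameters recorded as comment headers.
#' @return \code{read_dosage_file}: a \code{\link{dosage_data}};
#'   \code{write_dosage_file}: the path, invisibly.
#' @export
read_dosage_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^(ploidy|n\\.ind|n\\.mrk),", lines[i])) {
    kv <- strsplit(lines[i], ",")[[1]]
    hdr[[kv[1]]] <- as.integer(kv[2])
    i <- i + 1L
  }
  for (key in c("ploidy", "n.ind", "n.mrk")) {
    if (is.null(hdr[[key]])) {
      stop("missing header record '", key, "' in ", path, call. = FALSE)
    }
  }
  cols <- strsplit(lines[i], ",")[[1]]
  if (length(cols) != 3L + hdr$n.ind || cols[1] != "marker") {
    stop("malformed column header at line ", lineno[i], " of ", path,
         call. = FALSE)
  }
  body <- lines[-seq_len(i)]
  if (length(body) != hdr$n.mrk) {
    stop("expected ", hdr$n.mrk, " marker rows, found ", length(body),
         call. = FALSE)
  }
  parts <- strsplit(body, ",")
  nf <- lengths(parts)
  if (any(nf != length(cols))) {
    stop("inconsistent column count at line ",
         lineno[-seq_len(i)][which(nf != length(cols))[1]], " of ", path,
         call. = FALSE)
  }
  tab <- do.call(rbind, parts)
  dos <- suppressWarnings(
    matrix(as.integer(tab[, -(1:3), drop = FALSE]), nrow = nrow(tab)))
  colnames(dos) <- cols[-(1:3)]
  dosage_data(
    markers = data.frame(name = tab[, 1],
                         dP = as.integer(tab[, 2]),
                         dQ = as.integer(tab[, 3])),
    dosages = dos, m = hdr$ploidy)
}

#' @rdname read_dosage_file
#' @export
write_dosage_file <- function(dataset, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header(params), con)
  writeLines(c(paste0("ploidy,", dataset$m),
               paste0("n.ind,", dataset$n_ind),
               paste0("n.mrk,", dataset$n_mrk)), con)
  writeLines(paste(c("marker", "dP", "dQ", colnames(dataset$dosages)),
                   collapse = ","), con)
  for (k in seq_len(dataset$n_mrk)) {
    writeLines(paste(c(dataset$markers$name[k], dataset$markers$dP[k],
                       dataset$markers$dQ[k], dataset$dosages[k, ]),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read dosages from a VCF file
#'
#' Convenience converter: extracts allele dosages from an uncompressed VCF
#' with per-sample \code{DS} (rounded) or polyploid \code{GT} fields
#' (counting alternate alleles), for a declared ploidy.  Parental dosages
#' are taken from the two samples named by \code{parents}.
#'
#' @param path VCF path.
#' @param m ploidy.
#' @param parents character vector of the two parental sample names.
#' @return a \code{\link{dosage_data}} of the remaining (offspring)
#'   samples.
#' @export
read_vcf_dosage <- function(path, m, parents) {
  m <- check_ploidy(m)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stop("no #CHROM header in ", path, call. = FALSE)
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  if (!all(parents %in% samples)) {
    stop("parent samples not found in VCF: ",
         paste(setdiff(parents, samples), collapse = ", "), call. = FALSE)
  }
  body <- lines[!startsWith(lines, "#")]
  recs <- strsplit(body, "\t")
  one <- function(fields) {
    fmt <- strsplit(fields[9], ":")[[1]]
    vals <- strsplit(fields[-(1:9)], ":")
    if ("DS" %in% fmt) {
      ds <- vapply(vals, function(v) suppressWarnings(
        as.numeric(v[match("DS", fmt)])), numeric(1))
      as.integer(round(ds))
    } else if ("GT" %in% fmt) {
      vapply(vals, function(v) {
        gt <- v[match("GT", fmt)]
        if (grepl("\\.", gt)) return(NA_integer_)
        sum(as.integer(strsplit(gt, "[/|]")[[1]]) > 0L)
      }, integer(1))
    } else {
      stop("record without GT or DS field", call. = FALSE)
    }
  }
  dos <- t(vapply(recs, one, integer(length(samples))))
  colnames(dos) <- samples
  name <- vapply(recs, function(f) {
    if (f[3] != ".") f[3] else paste0(f[1], "_", f[2])
  }, character(1))
  ip <- match(parents, samples)
  dosage_data(
    markers = data.frame(name = name,
                         dP = as.integer(dos[, ip[1]]),
                         dQ = as.integer(dos[, ip[2]])),
    dosages = dos[, -ip, drop = FALSE], m = m)
}

#' Export a pairwise recombination-fraction scan
#'
#' Writes one row per unordered marker pair (the best-scoring phase), or
#' one row per evaluated phase partition when \code{all_phases = TRUE}:
#' marker1, marker2, r_hat, lod_linkage, wP, wQ, lod_phase.
#'
#' @param pw result of \code{\link{pairwise_rf_matrix}}.
#' @param path output path.
#' @param params named list recorded as comment headers.
#' @param all_phases write every evaluated partition, not only the best.
#' @return the path, invisibly.
#' @export
write_pairwise_file <- function(pw, path, params = list(),
                                all_phases = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header(params), con)
  writeLines("marker1\tmarker2\tr_hat\tlod_linkage\twP\twQ\tlod_phase", con)
  for (key in names(pw$scans)) {
    mm <- strsplit(key, "|", fixed = TRUE)[[1]]
    rows <- if (all_phases) pw$scans[[key]] else pw$scans[[key]][1]
    for (res in rows) {
      writeLines(sprintf("%s\t%s\t%.6f\t%.4f\t%d\t%d\t%.4f",
                         mm[1], mm[2], res$r_hat, res$lod_linkage,
                         res$phase[1], res$phase[2], res$lod_phase), con)
    }
  }
  invisible(path)
}

#' Write and read a phased map
#'
#' Tab-separated: marker name, position (Haldane cM), dP, dQ, m columns of
#' parent-P homolog indicators, m columns of parent-Q indicators, and the
#' recombination fraction to the next marker (NA on the last row).
#'
#' @param map a \code{\link{phase_chain}} result.
#' @param path file path.
#' @param params named list recorded as comment headers.
#' @return \code{write_phased_map}: the path invisibly;
#'   \code{read_phased_map}: a list with \code{markers}, \code{HP},
#'   \code{HQ}, \code{r}, \code{m}.
#' @export
write_phased_map <- function(map, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header(c(params, list(ploidy = map$m,
                                          loglik = map$loglik))), con)
  m <- map$m
  writeLines(paste(c("marker", "position", "dP", "dQ",
                     sprintf("P%d", 1:m), sprintf("Q%d", 1:m), "r_next"),
                   collapse = "\t"), con)
  z <- nrow(map$markers)
  rn <- c(map$r, NA)
  for (k in seq_len(z)) {
    writeLines(paste(c(map$markers$name[k],
                       sprintf("%.4f", map$markers$position[k]),
                       map$markers$dP[k], map$markers$dQ[k],
                       map$HP[, k], map$HQ[, k],
                       ifelse(is.na(rn[k]), "NA", sprintf("%.6f", rn[k]))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_phased_map
#' @export
read_phased_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  cols <- strsplit(lines[1], "\t")[[1]]
  m <- sum(grepl("^P[0-9]+$", cols))
  tab <- do.call(rbind, strsplit(lines[-1], "\t"))
  z <- nrow(tab)
  HP <- t(matrix(as.integer(tab[, 4 + (1:m)]), z, m))
  HQ <- t(matrix(as.integer(tab[, 4 + m + (1:m)]), z, m))
  r <- suppressWarnings(as.numeric(tab[, ncol(tab)]))
  list(markers = data.frame(name = tab[, 1],
                            position = as.numeric(tab[, 2]),
                            dP = as.integer(tab[, 3]),
                            dQ = as.integer(tab[, 4])),
       HP = HP, HQ = HQ, r = r[-z], m = m)
}

#' Write and read a simulation truth sidecar
#'
#' Records everything needed to evaluate a reconstructed map: the parental
#' homolog matrices and true recombination fractions as structured comment
#' records, then one row per offspring-marker with the transmitted homolog
#' subsets.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{simulate_population}}.
#' @param path file path.
#' @param marker_names marker names matching the simulated columns.
#' @return \code{write_truth_file}: the path invisibly;
#'   \code{read_truth_file}: a truth list.
#' @export
write_truth_file <- function(truth, path, marker_names = NULL) {
  m <- nrow(truth$HP)
  z <- ncol(truth$HP)
  if (is.null(marker_names)) marker_names <- sprintf("M%d", seq_len(z))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header(list(ploidy = m)), con)
  writeLines(paste0("#r\t", paste(sprintf("%.8f", truth$r), collapse = "\t")),
             con)
  for (k in seq_len(z)) {
    writeLines(paste0("#phase\t", marker_names[k], "\t",
                      paste(truth$HP[, k], collapse = ""), "\t",
                      paste(truth$HQ[, k], collapse = "")), con)
  }
  writeLines("ind\tmarker\tgameteP\tgameteQ", con)
  n <- length(truth$tracksP)
  for (ind in seq_len(n)) {
    for (k in seq_len(z)) {
      writeLines(paste(ind, marker_names[k],
                       paste(sort(truth$tracksP[[ind]][, k]), collapse = "|"),
                       paste(sort(truth$tracksQ[[ind]][, k]), collapse = "|"),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_truth_file
#' @export
read_truth_file <- function(path) {
  lines <- readLines(path)
  rline <- lines[startsWith(lines, "#r\t")]
  r <- as.numeric(strsplit(rline, "\t")[[1]][-1])
  ph <- strsplit(lines[startsWith(lines, "#phase\t")], "\t")
  tobits <- function(s) as.integer(strsplit(s, "")[[1]])
  HP <- vapply(ph, function(p) tobits(p[3]), tobits(ph[[1]][3]))
  HQ <- vapply(ph, function(p) tobits(p[4]), tobits(ph[[1]][4]))
  body <- lines[!startsWith(lines, "#")]
  tab <- do.call(rbind, strsplit(body[-1], "\t"))
  parse_sets <- function(col) {
    lapply(split(col, as.integer(tab[, 1])), function(v) {
      vapply(strsplit(v, "|", fixed = TRUE),
             function(x) as.integer(x), integer(nrow(HP) / 2))
    })
  }
  list(HP = HP, HQ = HQ, r = r,
       tracksP = parse_sets(tab[, 3]), tracksQ = parse_sets(tab[, 4]),
       markers = unique(tab[, 2]))
}
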