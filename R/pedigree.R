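#' Construct a three-generation pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `sex` (`"male"`, `"female"`, `"unknown"`), `generation`
#' (`"G1"`, `"G2"`, `"G3"`), `father_id`, `mother_id` (`NA` for founders),
#' `family` (pedigree label), and the parental ages at the individual's
#' birth, `dad_age` and `mom_age` (years, `NA` when unknown).
#'
#' Validation enforces the generational structure of a three-generation
#' cohort: every G3 individual must have both parents present as G2
#' individuals; G2 individuals may reference unsequenced G1 parents (a
#' referenced parent absent from the table), which downstream grandparental
#' checks skip.
#'
#' @param df data frame with at least `id`, `sex`, `father_id`, `mother_id`;
#'   `generation` is inferred from parent references when absent.
#' @param pedigree_id label for the cohort.
#' @return the validated pedigree (class `dnm_pedigree`).
#' @export
new_pedigree <- function(df, pedigree_id = "cohort") {
  stopifnot(is.data.frame(df), all(c("id", "sex", "father_id", "mother_id") %in% names(df)))
  df$id <- as.character(df$id)
  df$father_id <- as.character(df$father_id)
  df$mother_id <- as.character(df$mother_id)
  df$father_id[df$father_id %in% c("0", "")] <- NA_character_
  df$mother_id[df$mother_id %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$id)) stop("duplicate individual ids in pedigree")
  if (!all(df$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be one of 'male', 'female', 'unknown'")
  }
  if (is.null(df$family)) df$family <- pedigree_id
  if (is.null(df$dad_age)) df$dad_age <- NA_real_
  if (is.null(df$mom_age)) df$mom_age <- NA_real_
  if (any(stats::na.omit(c(df$dad_age, df$mom_age)) < 0)) {
    stop("parental ages must be nonnegative")
  }
  if (is.null(df$generation)) df$generation <- infer_generations(df)
  if (!all(df$generation %in% c("G1", "G2", "G3"))) {
    stop("generation must be G1, G2 or G3")
  }
  ## acyclicity / cross-generation checks
  g3 <- df[df$generation == "G3", , drop = FALSE]
  if (nrow(g3)) {
    pa <- match(g3$father_id, df$id)
    ma <- match(g3$mother_id, df$id)
    bad <- is.na(pa) | is.na(ma)
    if (any(bad)) {
      stop("G3 individuals with missing parent reference: ",
           paste(g3$id[bad], collapse = ", "))
    }
    if (!all(df$generation[pa] == "G2") || !all(df$generation[ma] == "G2")) {
      stop("G3 individuals must have G2 parents")
    }
  }
  g2 <- df[df$generation == "G2", , drop = FALSE]
  for (col in c("father_id", "mother_id")) {
    idx <- match(g2[[col]], df$id)
    present <- !is.na(g2[[col]]) & !is.na(idx)
    if (any(present) && !all(df$generation[idx[present]] == "G1")) {
      stop("G2 individuals must have G1 parents")
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("dnm_pedigree", "data.frame"),
            pedigree_id = pedigree_id)
}

infer_generations <- function(df) {
  ref_parent <- unique(stats::na.omit(c(df$father_id, df$mother_id)))
  founder <- is.na(df$father_id) & is.na(df$mother_id)
  gen <- ifelse(founder, "G1", NA_character_)
  ## parents present or referenced-but-absent founders -> child one level down
  for (pass in 1:3) {
    for (i in which(is.na(gen))) {
      pg <- c(gen[match(df$father_id[i], df$id)], gen[match(df$mother_id[i], df$id)])
      pg <- pg[!is.na(pg)]
      ## referenced but unsequenced parents count as G1
      absent <- sum(!c(df$father_id[i], df$mother_id[i]) %in% df$id)
      if (absent > 0) pg <- c(pg, rep("G1", absent))
      if (length(pg)) {
        gen[i] <- c(G1 = "G2", G2 = "G3", G3 = "G4")[[max(pg)]]
      }
    }
  }
  if (anyNA(gen) || any(gen == "G4")) stop("could not infer a three-generation structure")
  gen
}

#' @export
print.dnm_pedigree <- function(x, ...) {
  tab <- table(x$generation)
  cat(sprintf("<dnm_pedigree '%s'> %d individuals (%s) in %d famil%s\n",
              attr(x, "pedigree_id"), nrow(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(unique(x$family)),
              if (length(unique(x$family)) == 1) "y" else "ies"))
  invisible(x)
}

#' Decompose a pedigree into family units
#'
#' A family unit is one unique pair of second-generation parents together
#' with their third-generation children (the sibship). Pedigrees in which
#' two G2 siblings each married and had children therefore decompose into
#' multiple units, each with its own `family_id`.
#'
#' @param pedigree a [new_pedigree()] object.
#' @return data frame with `family_id`, `father_id`, `mother_id`,
#'   `n_children` and a list-column `children` of G3 sample ids. The units
#'   partition the G3 individuals.
#' @export
split_family_units <- function(pedigree) {
  g3 <- pedigree[pedigree$generation == "G3", , drop = FALSE]
  if (!nrow(g3)) {
    return(data.frame(family_id = character(), father_id = character(),
                      mother_id = character(), n_children = integer()))
  }
  key <- paste(g3$father_id, g3$mother_id, sep = "\r")
  sp <- split(g3$id, key)
  pairs <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  out <- data.frame(
    family_id = sprintf("FU%02d", seq_along(sp)),
    father_id = pairs[, 1],
    mother_id = pairs[, 2],
    n_children = lengths(sp),
    stringsAsFactors = FALSE
  )
  out$children <- unname(sp)
  out
}

#' Relatives exempt from the cohort-wide carrier screen
#'
#' The carrier screen removes putative DNMs whose allele is carried by
#' samples outside the candidate's immediate family. The exemption covers
#' parents, grandparents, siblings (sharing either parent), and descendants
#' (children and grandchildren) -- descendants must be exempt because a
#' transmitted DNM is, by design, carried by the candidate's own children.
#'
#' @param pedigree a pedigree.
#' @param id focal sample id.
#' @return character vector of exempt sample ids (including `id`).
#' @export
immediate_family <- function(pedigree, id) {
  row <- pedigree[pedigree$id == id, , drop = FALSE]
  if (!nrow(row)) stop("unknown sample id: ", id)
  parents <- stats::na.omit(c(row$father_id, row$mother_id))
  gparents <- unlist(lapply(parents, function(p) {
    pr <- pedigree[pedigree$id == p, , drop = FALSE]
    if (nrow(pr)) stats::na.omit(c(pr$father_id, pr$mother_id)) else character()
  }))
  sibs <- pedigree$id[
    (!is.na(pedigree$father_id) & pedigree$father_id %in% parents) |
    (!is.na(pedigree$mother_id) & pedigree$mother_id %in% parents)]
  kids <- children_of(pedigree, id)
  gkids <- unlist(lapply(kids, children_of, pedigree = pedigree))
  unique(c(id, parents, gparents, sibs, kids, gkids))
}

#' Children of an individual
#' @param pedigree a pedigree.
#' @param id sample id.
#' @return character vector of ids of children.
#' @export
children_of <- function(pedigree, id) {
  pedigree$id[(!is.na(pedigree$father_id) & pedigree$father_id == id) |
              (!is.na(pedigree$mother_id) & pedigree$mother_id == id)]
}

parents_of <- function(pedigree, id) {
  row <- pedigree[pedigree$id == id, , drop = FALSE]
  c(father = row$father_id[1], mother = row$mother_id[1])
}

#' Read a pedigree from a PED file (plus optional ages table)
#'
#' Standard 6-column tab-separated PED: family, individual, father, mother,
#' sex (1 = male, 2 = female, 0 = unknown), phenotype (ignored). Parental
#' ages at birth can be supplied as a CSV with columns
#' `child_id, dad_age, mom_age`.
#'
#' @param path PED file path.
#' @param ages optional path to the ages CSV.
#' @return a [new_pedigree()] object.
#' @export
read_ped <- function(path, ages = NULL) {
  ped <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("family", "id", "father_id",
                                         "mother_id", "sex", "phenotype"))
  df <- data.frame(
    id = ped$id,
    sex = c(`1` = "male", `2` = "female", `0` = "unknown")[ped$sex],
    father_id = ped$father_id,
    mother_id = ped$mother_id,
    family = ped$family,
    stringsAsFactors = FALSE
  )
  if (!is.null(ages)) {
    at <- utils::read.csv(ages, colClasses = c(child_id = "character"))
    m <- match(df$id, at$child_id)
    df$dad_age <- at$dad_age[m]
    df$mom_age <- at$mom_age[m]
  }
  new_pedigree(df)
}

#' Write a pedigree as PED (and optionally the ages CSV)
#' @param pedigree a pedigree.
#' @param path output PED path.
#' @param ages_path optional output path for the ages CSV.
#' @return invisibly, `path`.
#' @export
write_ped <- function(pedigree, path, ages_path = NULL) {
  sex <- c(male = "1", female = "2", unknown = "0")[pedigree$sex]
  out <- data.frame(pedigree$family, pedigree$id,
                    ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
                    ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
                    sex, "0")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(ages_path)) {
    keep <- !is.na(pedigree$dad_age) | !is.na(pedigree$mom_age)
    utils::write.csv(data.frame(child_id = pedigree$id[keep],
                                dad_age = pedigree$dad_age[keep],
                                mom_age = pedigree$mom_age[keep]),
                     ages_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
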