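#' Default radiomics feature manifest
#'
#' Builds the default manifest of 254 cardiac radiomics features: 78 shape
#' features spanning the left ventricle (LV), right ventricle (RV) and LV
#' myocardium (MYO), plus 35 first-order and 141 texture features extracted
#' from the LV myocardium only. Feature identifiers are opaque generated
#' names; a study-specific manifest can be supplied instead via
#' [read_manifest()].
#'
#' @param n_shape,n_first_order,n_texture Category sizes. Defaults give the
#'   standard 254-feature panel.
#' @return A data frame of class `feature_manifest` with columns
#'   `feature_id`, `category` (`shape`, `first_order`, `texture`) and
#'   `region` (`LV`, `RV`, `MYO`).
#' @examples
#' m <- default_manifest()
#' table(m$category)
#' @export
default_manifest <- function(n_shape = 78L, n_first_order = 35L,
                             n_texture = 141L) {
  regions <- rep_len(c("LV", "RV", "MYO"), n_shape)
  shape <- data.frame(
    feature_id = sprintf("shape_%s_%03d", regions, seq_len(n_shape)),
    category = "shape",
    region = regions,
    stringsAsFactors = FALSE
  )
  first_order <- data.frame(
    feature_id = sprintf("firstorder_MYO_%03d", seq_len(n_first_order)),
    category = "first_order",
    region = "MYO",
    stringsAsFactors = FALSE
  )
  texture <- data.frame(
    feature_id = sprintf("texture_MYO_%03d", seq_len(n_texture)),
    category = "texture",
    region = "MYO",
    stringsAsFactors = FALSE
  )
  validate_manifest(rbind(shape, first_order, texture))
}

#' Read and validate a feature manifest
#'
#' Reads a manifest from CSV (columns `feature_id`, `category`, `region`) or
#' JSON (array of objects with those fields) and validates it.
#'
#' @param path Path to a `.csv` or `.json` manifest file.
#' @return A validated `feature_manifest` data frame.
#' @export
read_manifest <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    m <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_manifest(m)
}

validate_manifest <- function(m) {
  required <- c("feature_id", "category", "region")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(m$feature_id)) {
    dup <- unique(m$feature_id[duplicated(m$feature_id)])
    stop("manifest has duplicated feature id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  bad_cat <- setdiff(unique(m$category), c("shape", "first_order", "texture"))
  if (length(bad_cat)) {
    stop("unknown feature category: ", paste(bad_cat, collapse = ", "))
  }
  bad_reg <- setdiff(unique(m$region), c("LV", "RV", "MYO"))
  if (length(bad_reg)) {
    stop("unknown region: ", paste(bad_reg, collapse = ", "))
  }
  m <- m[, required]
  class(m) <- c("feature_manifest", "data.frame")
  m
}

#' @export
print.feature_manifest <- function(x, ...) {
  cat("Radiomics feature manifest:", nrow(x), "features\n")
  print(table(category = x$category))
  invisible(x)
}

#' Default exposure catalogue for the phenome-wide association study
#'
#' Builds the default catalogue of 701 exposure variables in 13 categories:
#' 666 variables applicable to both sexes, 30 female-specific and 5
#' male-specific. The category a variable belongs to defines its Bonferroni
#' family: corrected p = raw p x (number of variables in the category for
#' that sex). The abdominal-MRI category holds 16 variables, so its
#' Bonferroni multiplier is 16; the remaining shared-category sizes are a
#' plausible allocation (real studies supply their own catalogue).
#'
#' @return A data frame of class `exposure_catalogue` with columns
#'   `variable_id`, `category` and `sex_applicability`
#'   (`both`, `female`, `male`).
#' @examples
#' cat <- default_exposure_catalogue()
#' nrow(cat)                     # 701
#' sum(cat$category == "Abdominal MRI")  # 16
#' @export
default_exposure_catalogue <- function() {
  sizes <- c(
    "Abdominal MRI" = 16L,
    "Blood biomarkers" = 60L,
    "Cognitive function" = 40L,
    "Education and employment" = 30L,
    "Early life factors" = 15L,
    "Health related outcomes" = 120L,
    "Lifestyle and environment" = 150L,
    "Mental health" = 60L,
    "Physical measures" = 100L,
    "Primary demographics" = 15L,
    "Self-reported health conditions" = 60L
  )
  stopifnot(sum(sizes) == 666L)
  shared <- data.frame(
    variable_id = unlist(lapply(names(sizes), function(cat) {
      sprintf("%s_%03d", gsub("[^A-Za-z]+", "_", tolower(cat)),
              seq_len(sizes[[cat]]))
    }), use.names = FALSE),
    category = rep(names(sizes), sizes),
    sex_applicability = "both",
    stringsAsFactors = FALSE
  )
  female <- data.frame(
    variable_id = sprintf("female_specific_%03d", 1:30),
    category = "Female specific",
    sex_applicability = "female",
    stringsAsFactors = FALSE
  )
  male <- data.frame(
    variable_id = sprintf("male_specific_%03d", 1:5),
    category = "Male specific",
    sex_applicability = "male",
    stringsAsFactors = FALSE
  )
  out <- rbind(shared, female, male)
  validate_catalogue(out)
}

validate_catalogue <- function(cat) {
  required <- c("variable_id", "category", "sex_applicability")
  missing <- setdiff(required, names(cat))
  if (length(missing)) {
    stop("catalogue is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cat$variable_id)) {
    stop("catalogue has duplicated variable id(s)")
  }
  bad <- setdiff(unique(cat$sex_applicability), c("both", "female", "male"))
  if (length(bad)) {
    stop("unknown sex_applicability: ", paste(bad, collapse = ", "))
  }
  cat <- cat[, required]
  class(cat) <- c("exposure_catalogue", "data.frame")
  cat
}

#' @export
print.exposure_catalogue <- function(x, ...) {
  cat("Exposure catalogue:", nrow(x), "variables in",
      length(unique(x$category)), "categories\n")
  print(table(sex = x$sex_applicability))
  invisible(x)
}
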