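#' Construct a keyword set
#'
#' A keyword set maps each lowercase keyword to one of the four categories
#' used for the query features: `symptom`, `disease`, `medication`,
#' `smoking`.
#'
#' @param keyword character vector of lowercase keywords (unique).
#' @param category character vector of categories, same length.
#' @return a `keyword_set` data.frame with columns `keyword`, `category`.
#' @export
keyword_set <- function(keyword, category) {
  keyword <- as.character(keyword)
  category <- as.character(category)
  if (length(keyword) != length(category)) {
    stop_invalid("`keyword` and `category` must have equal length")
  }
  if (anyDuplicated(keyword)) stop_invalid("keywords must be unique")
  if (any(keyword != tolower(keyword))) stop_invalid("keywords must be lowercase")
  ok <- category %in% c("symptom", "disease", "medication", "smoking")
  if (!all(ok)) {
    stop_invalid("invalid categories: %s",
                 paste(unique(category[!ok]), collapse = ", "))
  }
  structure(data.frame(keyword = keyword, category = category,
                       stringsAsFactors = FALSE),
            class = c("keyword_set", "data.frame"))
}

#' Default respiratory-illness keyword vocabulary
#'
#' An 88-keyword vocabulary over the four categories, shipped as the default
#' disease vocabulary of the synthetic query generator. It contains the
#' published example terms (e.g. cough, wheezing, migraine, anxiety; asthma,
#' copd, bronchitis, pneumonia, sepsis, sinus, emphysema; inhaler, advair,
#' symbicort, ventolin, proair; cigarette, nicotine, cigs, juul, vape) padded
#' with further plausible symptom, disease, medication and smoking terms.
#' The count of 88 is cosmetic realism, not a modelling constant.
#'
#' @return a `keyword_set` of 88 keywords.
#' @export
default_keywords <- function() {
  symptoms <- c("cough", "coughing", "wheezing", "wheeze", "migraine",
                "anxiety", "breathless", "breathlessness", "phlegm", "mucus",
                "congestion", "fatigue", "dizziness", "headache", "snoring",
                "hoarseness", "sneezing", "tightness", "palpitations",
                "heartburn", "dyspnea", "hyperventilation", "insomnia",
                "lightheaded", "chills", "nausea", "drowsiness", "exhaustion")
  diseases <- c("asthma", "copd", "bronchitis", "pneumonia", "sepsis",
                "sinus", "emphysema", "sinusitis", "influenza",
                "tuberculosis", "allergies", "rhinitis", "laryngitis",
                "pleurisy", "pneumonitis", "fibrosis", "apnea", "eczema",
                "hypertension", "diabetes")
  medications <- c("inhaler", "advair", "symbicort", "ventolin", "proair",
                   "albuterol", "flovent", "spiriva", "incruse", "ketamine",
                   "singulair", "montelukast", "prednisone", "pulmicort",
                   "xopenex", "salbutamol", "budesonide", "fluticasone",
                   "salmeterol", "nebulizer", "theophylline", "ipratropium",
                   "tiotropium", "breo", "trelegy")
  smoking <- c("smoking", "cigarette", "cigarettes", "nicotine", "cigs",
               "juul", "vape", "vaping", "tobacco", "ecig", "ecigs",
               "hookah", "menthol", "chantix", "nicorette")
  keyword_set(c(symptoms, diseases, medications, smoking),
              rep(c("symptom", "disease", "medication", "smoking"),
                  c(length(symptoms), length(diseases), length(medications),
                    length(smoking))))
}

#' Default background (non-disease) query vocabulary
#'
#' Everyday search terms used as the background token pool of the synthetic
#' query generator; disjoint from [default_keywords()].
#'
#' @param n optional number of words; if larger than the built-in list the
#'   pool is extended with generic tokens `bg001, bg002, ...`.
#' @return character vector of lowercase words.
#' @export
default_background_vocab <- function(n = NULL) {
  words <- c("weather", "news", "recipe", "pizza", "restaurant", "movie",
             "movies", "music", "lyrics", "game", "games", "score", "football",
             "basketball", "baseball", "soccer", "tickets", "flights", "hotel",
             "hotels", "maps", "directions", "traffic", "bus", "train", "taxi",
             "car", "cars", "truck", "bike", "insurance", "bank", "banking",
             "loan", "mortgage", "rent", "apartment", "apartments", "house",
             "houses", "jobs", "job", "salary", "resume", "interview",
             "school", "schools", "college", "university", "homework", "math",
             "science", "history", "english", "spanish", "translate",
             "dictionary", "calculator", "converter", "time", "date",
             "calendar", "email", "login", "password", "facebook", "youtube",
             "twitter", "instagram", "amazon", "ebay", "walmart", "target",
             "coupons", "deals", "sale", "shoes", "clothes", "dress", "shirt",
             "jacket", "watch", "phone", "phones", "laptop", "computer",
             "printer", "camera", "headphones", "charger", "battery", "wifi",
             "internet", "cable", "streaming", "series", "episode", "season",
             "actor", "actress", "celebrity", "horoscope", "quotes", "jokes",
             "memes", "wallpaper", "photos", "video", "videos", "chat",
             "dating", "wedding", "birthday", "gift", "gifts", "flowers",
             "garden", "gardening", "plants", "dog", "dogs", "cat", "cats",
             "pet", "pets", "vet", "zoo", "park", "beach", "camping",
             "hiking", "fishing", "golf", "gym", "yoga", "running",
             "workout", "diet", "calories", "coffee", "tea", "beer", "wine",
             "cocktail", "breakfast", "lunch", "dinner", "dessert", "cake",
             "cookies", "bread", "pasta", "salad", "soup", "chicken", "beef",
             "fish", "vegetarian", "grocery", "market", "pharmacy", "library",
             "museum", "concert", "festival", "lottery", "horoscopes",
             "crossword", "sudoku", "chess", "poker")
  if (!is.null(n) && n > length(words)) {
    words <- c(words, sprintf("bg%03d", seq_len(n - length(words))))
  } else if (!is.null(n)) {
    words <- words[seq_len(n)]
  }
  words
}

#' Read / write a keyword set as CSV
#'
#' Plain two-column CSV with header `keyword,category`.
#'
#' @param x a `keyword_set`.
#' @param path file path.
#' @return `read_keywords` returns a `keyword_set`; `write_keywords`
#'   (invisibly) the path.
#' @export
write_keywords <- function(x, path) {
  stopifnot(inherits(x, "keyword_set"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_keywords
#' @export
read_keywords <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  keyword_set(d$keyword, d$category)
}
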