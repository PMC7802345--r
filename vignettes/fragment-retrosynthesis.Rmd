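---
title: "Fragment-sentence retrosynthesis: model, curation, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-sentence retrosynthesis: model, curation, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea

Single-step retrosynthesis asks: given a product molecule, which reactants
could have produced it in one reaction? `fragretro` treats this as machine
translation between an artificial "fragment language". A molecule is not a
SMILES string here but the *set* of predefined substructures it contains
(MACCS keys, a dictionary of 166 SMARTS patterns). Writing the keys present
in a molecule as words, ordered by how common each key is in the reaction
corpus, turns every molecule into a short sentence; a reaction becomes a
sentence pair (product sentence to reactant sentence), and an
encoder–decoder network can learn the substructural edits that chemical
reactions perform. Because the output is a set of substructures rather than
a character-level SMILES, the model cannot produce syntactically invalid
molecules — the classic failure mode of string-based translation — and a
lookup table maps predicted key sets back to real molecules.

## The fragment language

**Key curation.** Not all 166 keys carry signal. Keys that never occur in
the reaction corpus, keys occurring below a rare-key threshold there, and
keys essentially absent from a reference corpus of drug-like molecules are
dropped. Both thresholds (`rare_primary`, `rare_reference`) default to
`1e-4` as a fraction of molecules; the cutoffs are configurable because
they depend on the corpus, and an explicit retained-key list can bypass
thresholding entirely. With the intended corpora this yields a 126-key
dictionary. Curation is recomputed from frequency profiles rather than
shipped as a fixed list, so the pipeline adapts to any corpus.

**Lettered words.** Retained keys are ranked by corpus frequency (rank 1 =
most frequent; ties broken toward the lower key index, so ranking is
deterministic). Ranks 1–21 take the 21 most frequent English letters
(E, T, A, O, I, N, S, H, R, D, L, C, U, M, W, F, G, Y, P, B, V) in upper
case, ranks 22–42 the same letters in lower case, ranks 43–84 repeat the 42
single-letter words with an "x" suffix, ranks 85–126 with a "z" suffix:
42 + 84 = 126 words, every word one or two characters. Whether the original
scheme alternated cases per rank or blocked all upper then all lower cannot
be settled from the description; the blocked assignment was chosen and is
fixed. Retained lists longer than 126 keys fall back to `w<rank>` words so
ECFP vocabularies also work.

**Sentences.** A molecule's sentence lists the words of its retained keys
in ascending rank (most frequent first); "frequency-sorted" and "ascending
order" describe the same ordering here, since rank 1 is the most frequent
word. Keys outside the dictionary are dropped silently — information loss
by design, the price of a small fixed vocabulary. Two-reactant targets are
joined with an en-dash separator, longer reactant first (ties broken
lexicographically on the token sequence). Four specials (`PAD`, `SOS`,
`EOS`, the separator) occupy the first four token ids.

## Corpus curation cascade

Raw reaction SMILES pass through, in order: parsing (reagents discarded,
components canonicalized), single-product filtering, sentence encoding,
duplicate removal (identity on the encoded sentence pair), internal-twin
removal (records whose product and reactant sentences are identical — the
chemical change is invisible at key resolution), a reactant-count limit
(at most 2), a pair-length limit (source plus target at most 100 tokens,
separator counted; the bound is inclusive, "set to 100" being read as
admitting length-100 pairs), and an injective collapse: when one product
sentence maps to several reactant sentences, only the shortest target
survives (ties lexicographic), making the training map a function. The
cascade order matters and is fixed; every stage updates a report whose
counts telescope exactly, which the tests verify against corpora with
known planted contamination. The curated set splits 90/10 into train/test
and 10% of train becomes validation, independently for the single-reactant,
double-reactant and combined subsets.

## The translator

A stacked LSTM encoder–decoder with Luong attention, written against
Armadillo with full backpropagation through time (`src/seq2seq.cpp`):

* **Encoder**: bidirectional by default (a unidirectional flag exists for
  the ablation), `num_layers` deep. The production-scale configuration is
  2 layers of 2000 hidden units with 126-dimensional embeddings; the desk
  experiments in this package use 1 layer of 64 units. Padded positions are
  handled by a masked state carry, so each sequence's final forward state
  is the one at its true length.
* **Bridge**: the description mentions bidirectional LSTMs for both encoder
  and decoder, but a generative decoder cannot condition on future output
  tokens; following standard NMT practice the decoder is unidirectional,
  and each encoder layer's final states (both directions concatenated) are
  projected through a learned `tanh` map to initialize the corresponding
  decoder layer.
* **Attention**: Luong's *general* (bilinear) score — the reference cites
  Luong without choosing among dot/general/concat — global over all source
  positions, or the local predictive variant: a learned sigmoid picks a
  center `p` in the source, only positions within `p ± D` (default
  `D = 10`) are attended, and a Gaussian penalty with `sigma = D/2` is
  added to the scores *inside the softmax*, so the weights always form a
  probability distribution over the attended window (Luong's original
  multiplies outside the softmax, which breaks normalization; the
  in-softmax form is equivalent up to renormalization and keeps the
  attention-weight invariant testable). The attentional state
  `h~ = tanh(Wc [context; h])` feeds the output softmax. Luong's
  input-feeding extension — concatenating `h~` to the next step's token
  embedding so the decoder can track coverage — is implemented behind the
  `input_feed` flag but off by default: the method description matches the
  base global-attention model, and on the desk-scale study the extra
  feedback path needs more epochs than the experiment budget to pay off.
* **Training**: teacher-forced cross-entropy (PAD masked), plain SGD,
  learning rate `lr * decay^floor((epoch-1)/3)` with defaults 4.0 and
  0.85, global gradient-norm clipping at 0.25, batch size 64, dropout 0.1
  between stacked layers. Batches are length-bucketed (shuffled, then
  sorted by source length within pools of eight batches) to limit padding
  waste; the pool order is reshuffled every epoch from the run seed.
* **Decoding**: greedy argmax until `EOS` or 102 tokens. Beam search is
  deliberately absent — the method's single deterministic prediction is a
  feature (no top-N ambiguity); repeated runs give identical output. A
  prediction keeps at most one separator; anything from a second separator
  on is truncated.

All gradients are verified against central-difference numerical
differentiation in the test suite, for bidirectional/unidirectional,
stacked, and local-attention configurations.

## Evaluation

Predicted and true reactant key sets are compared with the Tanimoto
coefficient `|R∩P| / |R∪P|`. With up to two reactants per side the pairing
is combinatorial: 2-vs-2 evaluates both bijective assignments and keeps the
better one, scored as the *mean* of its two pair similarities — the mean is
chosen so that an exact match requires both pairs exact; unequal counts
evaluate all cross pairs and keep the single best. Two empty key sets score
0 (with a warning), not 1: an empty prediction carries no structural
information. Corpus-level reporting uses the bands `<0.50`, `[0.50,0.70)`,
`[0.70,0.85]`, `(0.85,1)` (the strict "bioactively similar" band) and
`{1.0}` (exact); the third band is closed at 0.85 so the five bins
partition `[0,1]`, and the cumulative `Tc ≥ 0.85` figure is also reported.
Tversky and Dice variants are available (`α = β = 1` recovers Tanimoto,
`α = β = 0.5` Dice).

## Retrieval

A predicted sentence is only a key set; real molecules come from a lookup
table with one entry per canonical SMILES (key set, sentence, inverted
key → entry index). Near misses are found by discrepant-key count — the
size of the symmetric difference between the query and entry key sets —
with exact matches at discrepancy 0; the inverted index makes the search
linear in the number of entries sharing at least one key. Entries with an
identical key set are indistinguishable at MACCS resolution; a circular
(Morgan) fingerprint of radius 2 folded to 2048 bits re-ranks them by
Tanimoto similarity to a reference. At inference the only available
reference is the query product; evaluation may use the true reactant to
reproduce reference-style tables. Both modes are exposed and the choice is
the caller's.

## Fingerprint backends

MACCS keys come from OpenBabel's SMARTS dictionary (via ChemmineOB); its
on-bit numbering matches the conventional 1-based key numbers 1..166, and
key 0 never appears. Circular fingerprints are computed in the package: a
Morgan iteration over the molecular graph (initial atom invariants:
element, formal charge, heavy degree, bond-order sum) hashes every atom
environment of radius 0..r with 32-bit FNV-1a and folds modulo `nbits`.
Owning the implementation is what makes the bit-degeneracy analysis
possible: every on bit can be traced to the exact set of atom-environment
fragments (canonical sub-SMILES) that activated it, and the mean
fragments-per-bit statistic quantifies how much a hashed fingerprint
overloads its tokens — the diagnosis for why radius-2 ECFP tokens are
harder to translate than radius-1 or MACCS tokens. The bit values therefore
differ from other toolkits' ECFP implementations; all similarity
comparisons are internally consistent.

## The synthetic study

Real patent corpora are large and external; the package ships a generator
that emulates their statistical structure at desk scale. A packaged library
of 200 drug-like molecules (25 scaffolds × 8 substituents, all parseable)
provides realistic key-set statistics; the fixture vocabulary retains its
non-zero keys up to the 126-word cap (the library activates 99 of the 166
keys, so all of them are kept). Product key sets are drawn from the
library with a few frequency-weighted key toggles (corpus diversity lives
mostly in common substructures, as in real collections; up to 4 toggles
per product). Five toy rules play the role of reaction templates, operating
directly on key sets — legitimate because the translation machinery never
inspects atoms after encoding. Four rules fire on a trigger key (first
match in priority order wins, so the product→reactant map is a
deterministic function); they drop their trigger and add fixed mid-rank
keys; one splits the key set at a rank threshold into two reactants (a
prefix/suffix split of the rank-ordered sentence, the kind of partition a
substructural disconnection induces); the default rule toggles a fixed
key, so no record is ever an internal twin by construction. Products are
rejection-sampled so the five rules contribute comparable shares — a
designed learnability fixture should test every rule with similar support
rather than conflate rule difficulty with data volume; the rule remains a
deterministic function of the product key set. Optional contamination plants known numbers of duplicates,
twins, 3-reactant records, over-long pairs and injectivity violations for
cascade testing, with the planted counts returned.

What the generator does *not* emulate: chemical validity of the toy edits,
the long-tail key-frequency distribution of patent data, many-to-one
product–reactant ambiguity beyond the planted violations, and corpus sizes
beyond a few thousand records. Passing the learnability test therefore
shows that the architecture, training loop and evaluation machinery work
end to end on rule-structured data — not that the model reaches any
particular accuracy on real reaction corpora, which require the full-scale
corpus and days of GPU training. The full-scale experiment runs through
exactly the same pipeline functions, only with larger configuration values.

**Problem sizes used in the checks.** The learnability experiment trains a
1-layer bidirectional model (64 hidden units, 64-dimensional embeddings)
on 2,000 generated pairs from the 5 default rules, evaluates exact matches
(`Tc = 1` under the pairing rule) on 200 held-out pairs, and compares the
unidirectional variant under the identical budget; training uses SGD with
lr 2 decayed 0.85 every 5 epochs, clip 2, batch size 8, 40 epochs. These
sizes were chosen as the smallest at which rule learning is clearly
demonstrable. Curation checks use a 300-record corpus with planted
contamination; retrieval checks a lookup over 1,000 sampled library
molecules.

## Numerical choices and degenerate inputs

* Softmax and attention computations subtract per-column maxima; masked
  positions score `-1e30`.
* Weights initialize uniformly in (−0.08, 0.08) from the R RNG; every
  stochastic step (init order, shuffling, dropout streams) derives from the
  run seed, so runs are bit-reproducible on one platform (floating-point
  nondeterminism across BLAS builds is the usual caveat).
* An empty encoded sentence (all keys curated away) is legal at encoding
  and scores 0 downstream; `translateSentences` returns an empty string
  for an empty source rather than decoding from nothing.
* Unparseable SMILES: profile and lookup construction skip-and-log;
  single-molecule operations raise an error naming the offending string.
* A key set is a set: duplicate words in a decoded sentence collapse, and
  out-of-order words decode to the same key set — evaluation is
  deliberately insensitive to token order, matching the set semantics of
  the representation.

## Known limitations

* MACCS definitions follow OpenBabel; a few exotic patterns differ from
  other toolkits, so absolute key sets (not the pipeline's behavior) can
  differ across toolkits.
* The in-package circular fingerprint is not bit-compatible with other
  ECFP implementations (by design, see above).
* The lookup table is an in-memory desk-scale structure (≤ ~1M entries);
  no external index is provided.
* No Transformer, beam search, data augmentation, or multi-GPU training;
  the translator is the reference architecture, scaled by configuration.
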