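# ADL script grammar

The ADL script is UTF-8 plain text. `#` starts a comment (to end of line);
blank lines are ignored. Four sections appear in this order. This grammar is
one consistent, deterministic dialect of the script fragments the format was
reconstructed from; see the package vignette for the reasoning behind each
choice.

```
script        = days-section activities-section behaviours-section noise-section

days-section  = "DAYS" NL natural NL

activities-section = "ACTIVITIES" NL *activity
activity      = name SP natural NL 1*pattern        ; natural = number of patterns
pattern       = probability 1*(SP step) NL
step          = sensor-name "@" lapse-seconds       ; first step lapse MUST be 0
                                                    ; lapse = seconds after the
                                                    ; previous activation (mean of
                                                    ; a Gaussian at simulation time)

behaviours-section = "BEHAVIOURS" NL *behaviour-model
behaviour-model    = "Prob" SP probability NL 1*(sequence / alteration)
sequence      = "S" SP time-slot 1*(SP seq-item) NL
seq-item      = activity-name "@" lapse-seconds     ; first item lapse MUST be 0
                                                    ; lapse = seconds after the
                                                    ; previous activity's END
alteration    = "A" SP probability SP time-slot SP activity-name NL

noise-section = "NOISE" NL *noise-line
noise-line    = sensor-name SP probability NL       ; per-hour activation probability

time-slot     = clock SP dash SP clock / clock dash clock
clock         = 1*2DIGIT ":" 2DIGIT [":" 2DIGIT]    ; 24:00 allowed as an end
dash          = "-" / "–"                           ; hyphen or en dash
probability   = decimal in [0, 1]
lapse-seconds = non-negative integer
```

Validation (beyond syntax): pattern probabilities of each activity and the
behaviour-model probabilities of the script must each sum to 1 (tolerance
1e-6); every referenced activity must be defined; every sensor used in a
pattern or noise line must be declared in the context-knowledge file.
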