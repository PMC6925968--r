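region,households,women_15_49,women_with_recent_birth
Arusha,418,420,216
Dar es salaam,700,797,341
Dodoma,420,343,197
Geita,431,535,303
Iringa,415,340,163
Kagera,439,416,239
Katavi,401,466,315
Kigoma,432,491,279
Kilimanjaro,449,370,130
Lindi,423,380,185
Manyara,426,434,251
Mara,438,531,321
Mbeya,410,374,192
Morogoro,398,345,194
Mtwara,410,348,161
Mwanza,406,496,254
Njombe,406,359,185
Pwani,385,333,184
Rukwa,436,425,272
Ruvuma,434,383,214
Shinyanga,421,516,311
Simiyu,420,587,372
Singida,438,413,245
Tabora,426,560,338
Tanga,426,465,216
National,10808,11127,6078
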