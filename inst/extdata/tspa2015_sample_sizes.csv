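region,facilities,facilities_anc,facilities_anc_obs,providers_obs,client_obs,first_visit_obs
Arusha,45,39,32,42,147,63
Dar es salaam,87,49,33,42,159,70
Dodoma,48,45,38,60,218,42
Geita,35,30,27,33,92,70
Iringa,39,36,32,37,125,61
Kagera,44,41,37,61,236,101
Katavi,35,32,24,34,132,88
Kigoma,41,40,30,43,181,41
Kilimanjaro,52,43,27,38,140,111
Lindi,37,37,35,48,190,70
Manyara,33,32,24,37,127,107
Mara,41,38,38,51,217,46
Mbeya,53,51,22,38,116,32
Morogoro,49,46,25,30,88,76
Mtwara,37,34,27,36,145,76
Mwanza,46,36,34,40,147,51
Njombe,39,37,42,44,164,47
Pwani,41,34,27,30,107,45
Rukwa,37,34,29,38,124,98
Ruvuma,42,41,33,49,196,33
Shinyanga,35,28,28,34,100,27
Simiyu,34,31,20,22,69,54
Singida,37,32,25,32,129,59
Tabora,44,42,26,34,133,75
Tanga,47,41,26,41,159,64
National,1078,949,741,994,3641,1607
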