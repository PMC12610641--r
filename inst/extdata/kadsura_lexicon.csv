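attribute,reference,definition
Citrus,0.01% D-Limonene in PG,"Fresh, peel-like zest reminiscent of lemon or orange."
Minty,0.01% L-Menthol in water,"Cooling, herbal note with a refreshing sensation."
Woody,0.1% Cedrol in PG,"Resinous, bark-like aroma evoking pine or sandalwood."
Floral,0.02% Linalool in PG,"Sweet, blossom-like scent similar to rose or jasmine."
Coconut-milk,Coconut juice,"Creamy, lactonic sweetness akin to coconut or peach."
Herbal,"0.05% 1,8-Cineole in PG","Green, medicinal character reminiscent of eucalyptus or grass."
Spicy,0.02% eugenol in PG,"Pungent, warm note suggestive of pepper or clove."
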