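drug_id	study_id	date	diseases
posaconazole	s01	1998	candidiasis
posaconazole	s02	2001	candidiasis;aspergillosis
posaconazole	s03	2003	aspergillosis
posaconazole	s04	2004	candidiasis
posaconazole	s05	2005	aspergillosis
posaconazole	s06	2005	zygomycosis
posaconazole	s07	2006	candidiasis;zygomycosis
posaconazole	s08	2006	aspergillosis
posaconazole	s09	2007	fusariosis
posaconazole	s10	2008	candidiasis
posaconazole	s11	2008	aspergillosis;fusariosis
posaconazole	s12	2009	candidiasis
posaconazole	s13	2009	aspergillosis
posaconazole	s14	2009	zygomycosis
posaconazole	s15	2009	fusariosis
posaconazole	s16	2010	candidiasis
posaconazole	s17	2010	aspergillosis
posaconazole	s18	2010	candidiasis
posaconazole	s19	2010	zygomycosis
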