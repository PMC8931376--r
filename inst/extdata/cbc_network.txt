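# Compartmentalized atom-mapped network for photosynthetic carbon metabolism.
# Compartment suffixes: .p plastid, .c cytosol, .m mitochondrion, .v vacuole.
# Untagged species are external sources/sinks (CO2in feed, unlabeled entries
# GLCu/TPu/CO2u/STARCHu, and the STARCH/SUCX/TRIOX/CO2out sinks).
# Grammar: id: S1 [+ S2] -> P1 [+ P2] , map ; reversible|irreversible
#
# --- CO2 feed and internal CO2 pool ---
co2_in: CO2in -> CO2.p , a -> a ; irreversible
co2_efflux: CO2.p -> CO2out , a -> a ; irreversible
# --- Calvin-Benson cycle (plastid) ---
rubisco_c: RUBP.p + CO2.p -> PGA.p + PGA.p , abcde + f -> fba + cde ; irreversible
rubisco_o: RUBP.p -> 2PG.p + PGA.p , abcde -> ba + cde ; irreversible
pga_red: PGA.p -> GAP.p , abc -> abc ; irreversible
tpi_p: GAP.p -> DHAP.p , abc -> abc ; reversible
fba_p: DHAP.p + GAP.p -> FBP.p , cba + def -> cbadef ; reversible
fbpase_p: FBP.p -> F6P.p , abcdef -> abcdef ; irreversible
tk1: F6P.p + GAP.p -> E4P.p + XU5P.p , abcdef + ghi -> cdef + abghi ; reversible
sba: DHAP.p + E4P.p -> SBP.p , cba + defg -> cbadefg ; reversible
sbpase: SBP.p -> S7P.p , abcdefg -> abcdefg ; irreversible
tk2: S7P.p + GAP.p -> R5P.p + XU5P.p , abcdefg + hij -> cdefg + abhij ; reversible
rpi: R5P.p -> RU5P.p , abcde -> abcde ; reversible
rpe_p: XU5P.p -> RU5P.p , abcde -> abcde ; reversible
prk: RU5P.p -> RUBP.p , abcde -> abcde ; irreversible
# --- starch synthesis (plastid) ---
pgi_p: F6P.p -> G6P.p , abcdef -> abcdef ; reversible
adpgs: G6P.p -> ADPG.p , abcdef -> abcdef ; irreversible
starch_syn: ADPG.p -> STARCH , abcdef -> abcdef ; irreversible
# --- envelope transport ---
tpt: DHAP.p -> DHAP.c , abc -> abc ; reversible
xpt: XU5P.c -> XU5P.p , abcde -> abcde ; irreversible
# --- photorespiration (lumped; C1 of one glycine lost as CO2) ---
pglp: 2PG.p -> GLY.m , ab -> ab ; irreversible
gdc: GLY.m + GLY.m -> SER.m + CO2.p , ab + cd -> cdb + a ; irreversible
ser_ga: SER.m -> GA.c , abc -> abc ; irreversible
ga_pga: GA.c -> PGA.p , abc -> abc ; irreversible
# --- sucrose synthesis (cytosol) ---
tpi_c: DHAP.c -> GAP.c , abc -> abc ; reversible
fba_c: DHAP.c + GAP.c -> FBP.c , cba + def -> cbadef ; reversible
fbpase_c: FBP.c -> F6P.c , abcdef -> abcdef ; irreversible
pgi_c: F6P.c -> G6P.c , abcdef -> abcdef ; reversible
ugp: G6P.c -> UDPG.c , abcdef -> abcdef ; irreversible
sps: UDPG.c + F6P.c -> SUC.c , abcdef + ghijkl -> abcdefghijkl ; irreversible
suc_export: SUC.c -> SUCX , abcdefghijkl -> abcdefghijkl ; irreversible
# --- cytosolic G6P shunt (oxidative PPP; C1 lost as CO2) ---
shunt: G6P.c -> RU5P.c + CO2.p , abcdef -> bcdef + a ; irreversible
rpe_c: RU5P.c -> XU5P.c , abcde -> abcde ; reversible
# --- efflux toward TCA / amino acid metabolism ---
triose_efflux: DHAP.c -> TRIOX , abc -> abc ; irreversible
# --- sucrose recycling and vacuolar sugar pools (orange path) ---
inv_c: SUC.c -> GLC.c + FRC.c , abcdefghijkl -> abcdef + ghijkl ; irreversible
hxk: GLC.c -> G6P.c , abcdef -> abcdef ; irreversible
frk: FRC.c -> F6P.c , abcdef -> abcdef ; irreversible
suc_tono: SUC.c -> SUC.v , abcdefghijkl -> abcdefghijkl ; reversible
inv_v: SUC.v -> GLC.v + FRC.v , abcdefghijkl -> abcdef + ghijkl ; irreversible
glc_tono: GLC.v -> GLC.c , abcdef -> abcdef ; irreversible
frc_tono: FRC.v -> FRC.c , abcdef -> abcdef ; irreversible
# --- hypothesis-variant entry reactions ---
e1_glc: GLCu -> G6P.c , abcdef -> abcdef ; irreversible
e2_glc: GLCu -> G6P.p , abcdef -> abcdef ; irreversible
e3_co2: CO2u -> CO2.p , a -> a ; irreversible
e4_tp: TPu -> DHAP.p , abc -> abc ; irreversible
starch_to: STARCHu -> G6P.p , abcdef -> abcdef ; irreversible
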