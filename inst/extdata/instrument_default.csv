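item_id,kind,source_tool,response_domain,merged_from,app_animal_baseline,app_human_baseline,app_animal_treatment,app_human_treatment,text,operationalisation
A1a,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Experimental groups,Reported when it is clear which groups were subject to which experimental conditions.
A1b,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Unit of analysis,Reported when the unit of analysis is clear; repeated measures need an explicit handling strategy.
A2a,RQ,ARRIVE,YN,A3c;CB3;C13a;C13b;C16,TRUE,TRUE,TRUE,TRUE,Exact n per group and in total,Reported when exact group and total sample sizes are given; ranges do not count.
A2b,RQ,ARRIVE,YN,C7a,TRUE,TRUE,TRUE,TRUE,A priori sample size calculation,Any report of an a-priori sample size justification counts as reported.
A3a,RQ,ARRIVE,YN,C4a,TRUE,TRUE,TRUE,TRUE,Inclusion criteria,Explicit eligibility criteria required; demographic description alone does not count.
A3b,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Excluded data points,Any explicit statement of exclusions counts as reported.
A6a,RQ,ARRIVE,YN,C6b,TRUE,TRUE,TRUE,TRUE,All assessed outcome measures,All assessed outcome measures must be explicitly listed.
A6b,RQ,ARRIVE,YNI,A10a;A10b;C6a;C17a;C17b,TRUE,TRUE,TRUE,TRUE,Primary outcome measure,The primary outcome (or the one used for the sample size calculation) must be explicit; irrelevant when no primary outcome can exist.
A7a,RQ,ARRIVE,YNI,C12a,TRUE,TRUE,TRUE,TRUE,Statistical methods,Both the statistical methods and the software must be named.
A7b,RQ,ARRIVE,YNI,,TRUE,TRUE,TRUE,TRUE,Statistical assumption tests,Explicit or implicit mention of assumption testing counts as reported.
A9a,RQ,ARRIVE,YN,A8a;A8b;C5,TRUE,TRUE,TRUE,TRUE,Methods: what was done,Reported when the description would allow reproduction: species/strain or population with age and sex and health status.
A9b,RQ,ARRIVE,YN,C14a,TRUE,TRUE,TRUE,TRUE,When the experiments were performed,Timing must be identifiable to the day; a month range does not count.
A9c,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Where the experiments were performed,The specific laboratory must be identifiable; an institution with many laboratories does not count.
A9d,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Rationale for the experimental design,At least two parts of the design must be explicitly justified.
A11,RQ,ARRIVE,YN,C1b,TRUE,TRUE,TRUE,TRUE,Abstract completeness,Not reported when any required element (mostly strain and sex) is missing from the abstract; strain ignored for human studies.
A12a,RQ,ARRIVE,YN,C2a,TRUE,TRUE,TRUE,TRUE,Background of the research question,Reported when the research question and its relevance are understandable.
A12b,RQ,ARRIVE,YNI,C2b,TRUE,FALSE,TRUE,TRUE,Animal model relevance,Model validity must be explicitly described; not scored for human baseline studies.
A13,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Objectives,The study objectives must be clear.
A14,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Ethical review,The ethics committee name and the approval number must both be provided.
A15,RQ,ARRIVE,YNI,,TRUE,FALSE,TRUE,FALSE,Housing and husbandry,Housing must be described well enough to picture the cage; a named standard type can suffice. Not scored for human studies.
A16a,RQ,ARRIVE,YNI,,TRUE,FALSE,TRUE,FALSE,Welfare-related refinements,Any refinement beyond anaesthesia counts. Not scored for human studies.
A16b,RQ,ARRIVE,YN,C19,TRUE,TRUE,TRUE,TRUE,Adverse events,Any mention of (absence of) adverse events counts as reported.
A16c,RQ,ARRIVE,YNI,,TRUE,FALSE,TRUE,FALSE,Humane endpoints,Any mention counts. Not scored for human studies.
A17a,RQ,ARRIVE,YN,C22,TRUE,TRUE,TRUE,TRUE,Interpretation of the results,Interpretation must relate explicitly to theory or prior literature; a bare result overview does not count.
A17b,RQ,ARRIVE,YN,C20,TRUE,TRUE,TRUE,TRUE,Limitations,One explicit or two implicit mentions of limitations count as reported.
A18,RQ,ARRIVE,YNI,C21,TRUE,TRUE,TRUE,TRUE,Generalisability,The extent of external validity must be described at least implicitly.
A20,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Data availability,Reported when the data are actually available where stated.
A21a,RQ,ARRIVE,YN,,TRUE,TRUE,TRUE,TRUE,Conflicts of interest,Explicit statement of conflicts or of their absence.
A21b,RQ,ARRIVE,YN,C25,TRUE,TRUE,TRUE,TRUE,Funding,Not reported when any required element (mostly funder involvement) is missing.
C1a,RQ,CONSORT,YN,,TRUE,TRUE,TRUE,TRUE,Type of study in the title,The title must name the type of study; a generic label does not count.
C3a,RQ,CONSORT,YN,,TRUE,TRUE,TRUE,TRUE,Type of experimental design,The experimental design must be named in the text.
C3b,RQ,CONSORT,YN,,TRUE,TRUE,TRUE,TRUE,Protocol violations,(Absence of) protocol deviations must be explicitly mentioned.
C4b,RQ,CONSORT,YN,,TRUE,TRUE,TRUE,TRUE,Study setting,More lenient than the laboratory item: certainty about the type of setting suffices.
C7b,RQ,CONSORT,YNI,C14b,TRUE,TRUE,TRUE,TRUE,Interim analyses and stopping rules,Any mention counts; irrelevant for single-measurement studies of explicitly short duration.
C8b,RQ,CONSORT,YNI,CB1,FALSE,FALSE,TRUE,TRUE,Type of randomisation,The type of randomisation must be named; irrelevant for studies without an intervention.
C10,RQ,CONSORT,YN,,FALSE,FALSE,TRUE,TRUE,Allocation roles,It must be clear who performed each step of group allocation; irrelevant for studies without an intervention.
C12b,RQ,CONSORT,YNI,C18,TRUE,TRUE,TRUE,TRUE,Additional analyses,Minimal description of methods for additional analyses; irrelevant when a single analysis was prespecified.
C15,RQ,CONSORT,YN,,TRUE,TRUE,TRUE,TRUE,Baseline values,Group-level baseline data required for at least age or weight plus genetics.
S1,RoB,SYRCLE,LUHI,A4a;C8a,FALSE,FALSE,TRUE,TRUE,Sequence generation (selection bias),Vague randomisation descriptions score unclear; irrelevant for studies without an intervention.
S2,RoB,SYRCLE,LUH,CB2,TRUE,TRUE,TRUE,TRUE,Baseline group differences,Low requires comparable baseline data for at least age or weight plus sex and genetic background or mutation type.
S3,RoB,SYRCLE,LUHI,A5;C9,TRUE,FALSE,TRUE,TRUE,Allocation concealment,Low requires adequate blinding of the investigator allocating subjects; irrelevant for human studies without an intervention.
S4,RoB,SYRCLE,LUHI,A4b,TRUE,FALSE,TRUE,FALSE,Animal housing (performance bias),Bias related to housing placement; irrelevant for human studies.
S5,RoB,SYRCLE,LUH,C11a;C11b,TRUE,TRUE,TRUE,TRUE,Blinding of participants and caregivers and investigators,Low requires adequate blinding of everyone performing or caring during the experiments.
S6,RoB,SYRCLE,LUH,CB4,TRUE,TRUE,TRUE,TRUE,Order of outcome assessment (detection bias),Bias related to the order or method of outcome assessment.
S7,RoB,SYRCLE,LUH,,TRUE,TRUE,TRUE,TRUE,Blinding of outcome assessors,Low requires all outcome assessors adequately blinded.
S8,RoB,SYRCLE,LUH,,TRUE,TRUE,TRUE,TRUE,Incomplete outcome data (attrition bias),Low requires explicitly complete data or incompleteness balanced across groups.
S9,RoB,SYRCLE,LUH,A19;CB5;C23;C24,TRUE,TRUE,TRUE,TRUE,Selective outcome reporting,Scored high whenever no protocol was posted; stricter than the source tool.
S10,RoB,SYRCLE,LUH,,TRUE,TRUE,TRUE,TRUE,Other sources of bias,High when the methods are unclear or concerning at points not covered by other items.
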