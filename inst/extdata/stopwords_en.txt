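# Frozen English stopword list. Personal pronouns (subject, object,
# possessive and reflexive forms) are deliberately absent: first-, second-
# and third-person pronouns are retained during preprocessing because
# pronoun usage is informative for mental-health text classification.
a
about
above
after
again
against
all
am
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
can
could
did
do
does
doing
down
during
each
few
for
from
further
had
has
have
having
here
how
if
in
into
is
just
more
most
no
nor
not
now
of
off
on
once
only
or
other
ought
out
over
own
s
same
should
so
some
such
t
than
that
the
then
there
these
this
those
through
to
too
under
until
up
very
was
were
what
when
where
which
while
who
whom
why
will
with
would
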